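test_that("ORF finding picks the longest ATG-to-stop run", {
  expect_null(find_orf("CCC"))
  orf <- find_orf("ATGAAATAA")
  expect_equal(orf$start, 0)
  expect_equal(orf$end, 9)
  expect_equal(orf$protein, "MK")

  # 30-nt ORF beats a 12-nt ORF in another position
  seq <- paste0("ATGAAATAA", "C", test_cds(9))   # 9 + 1 + 30
  expect_equal(find_orf(seq)$end - find_orf(seq)$start, 30)

  # ties resolve 5'-most
  two <- paste0(test_cds(4), "C", test_cds(4))
  expect_equal(find_orf(two)$start, 0)

  # N blocks start and stop codon matching
  expect_null(find_orf("ATGAAATNA"))
  expect_error(find_orf("ATGXAATAA"), "invalid nucleotide")
})

test_that("coding potential thresholds at 0.725 and uses external scores", {
  expect_true(coding_potential("x", external_score = 0.73)$is_coding)
  expect_false(coding_potential("x", external_score = 0.72)$is_coding)

  no_orf <- coding_potential(strrep("C", 300))
  expect_false(no_orf$is_coding)
  expect_equal(no_orf$score, 0)

  long_cds <- paste0(strrep("C", 50), test_cds(120, "GAA"), strrep("C", 50))
  cp <- coding_potential(long_cds)
  expect_true(cp$is_coding)
  expect_true(cp$score > 0.725 && cp$score <= 1)
})

test_that("NMD sensitivity follows the 50-nt last-junction rule", {
  orf9 <- list(start = 0, end = 9)
  single <- single_exon_model("t1", "ATGAAATAAC")
  expect_false(detect_nmd(single, list(start = 0, end = 9)))

  two_exon <- function(gap_after_stop, last_exon = 40) {
    w1 <- 9 + gap_after_stop
    seq <- paste0("ATGAAATAA", strrep("C", gap_after_stop + last_exon))
    transcript_model("t", "g", "+",
                     cbind(c(0, w1 + 100), c(w1, w1 + 100 + last_exon)),
                     seq)
  }
  expect_true(detect_nmd(two_exon(55), orf9))    # junction 55 nt past stop
  expect_false(detect_nmd(two_exon(10), orf9))
  expect_false(detect_nmd(two_exon(50), orf9))   # rule is strictly > 50
  expect_error(detect_nmd(single, list(start = 0, end = 99)), "outside")
})

test_that("NMD agrees with an exhaustive junction oracle on random models", {
  set.seed(8)
  for (rep in 1:200) {
    n_ex <- sample(2:5, 1)
    widths <- sample(30:120, n_ex, replace = TRUE)
    introns <- sample(50:200, n_ex - 1, replace = TRUE)
    starts <- cumsum(c(0, widths[-n_ex] + introns))
    m <- transcript_model("t", "g", "+", cbind(starts, starts + widths),
                          strrep("A", sum(widths)))
    orf_end <- sample(seq(3, sum(widths), 3), 1)
    orf <- list(start = 0, end = orf_end)
    # oracle: last junction sits at total length minus final exon width
    oracle <- (sum(widths) - widths[n_ex] - orf_end) > 50
    expect_identical(detect_nmd(m, orf), oracle)
  }
})

test_that("splice events classify against hand-built structures", {
  mk <- function(id, exons, strand = "+", gene = "g") {
    transcript_model(id, gene, strand, exons)
  }
  same <- classify_splice_events(mk("a", cbind(0, 100)),
                                 mk("b", cbind(0, 100)))
  expect_equal(nrow(same), 0)

  # intron retention: single exon of B spans A's intron plus both flanks
  ir <- classify_splice_events(mk("a", cbind(c(0, 200), c(100, 300))),
                               mk("b", cbind(0, 300)))
  expect_true(any(ir$event == "intron_retention" & ir$isoform == "b"))
  expect_false(any(ir$event %in% c("alt_5prime", "alt_3prime")))

  # alt TSS: differing outermost 5' boundary, plus strand
  tss <- classify_splice_events(
    mk("a", cbind(c(0, 200), c(100, 300))),
    mk("b", cbind(c(50, 200), c(100, 300))))
  expect_equal(tss$event, "alt_tss")

  # on the minus strand the same structural change is an alt TTS
  tss_minus <- classify_splice_events(
    mk("a", cbind(c(0, 200), c(100, 300)), "-"),
    mk("b", cbind(c(50, 200), c(100, 300)), "-"))
  expect_equal(tss_minus$event, "alt_tts")

  # exon skipping: middle exon of A inside B's intron
  sk <- classify_splice_events(
    mk("a", cbind(c(0, 150, 300), c(100, 200, 400))),
    mk("b", cbind(c(0, 300), c(100, 400))))
  expect_true(any(sk$event == "exon_skipping" & sk$isoform == "a"))

  # alt 3' site: internal acceptor shift on the plus strand
  a3 <- classify_splice_events(
    mk("a", cbind(c(0, 200, 400), c(100, 300, 500))),
    mk("b", cbind(c(0, 230, 400), c(100, 300, 500))))
  expect_true("alt_3prime" %in% a3$event)

  expect_error(classify_splice_events(mk("a", cbind(0, 10)),
                                      mk("b", cbind(0, 10), "-")),
               "strand")
})

test_that("splice classification is symmetric up to a/b polarity", {
  gm <- simulate_gene_models(n_genes = 12, seed = 41)
  for (i in seq_len(nrow(gm$truth))) {
    a <- gm$models[[gm$truth$iso_before[i]]]
    b <- gm$models[[gm$truth$iso_after[i]]]
    ab <- classify_splice_events(a, b)
    ba <- classify_splice_events(b, a)
    flip <- c(a = "b", b = "a")
    ba$isoform <- unname(flip[ba$isoform])
    expect_setequal(paste(ab$event, ab$isoform), paste(ba$event, ba$isoform))
  }
})

test_that("domain scanning reports all (overlapping) motif hits", {
  lib0 <- data.frame(name = character(0), motif = character(0))
  expect_equal(nrow(identify_domains("AAMKAA", lib0)), 0)

  lib <- data.frame(name = c("m1", "m2"), motif = c("MK", "KA"))
  hits <- identify_domains("AAMKAA", lib[1, , drop = FALSE])
  expect_equal(hits$position, 2L)

  both <- identify_domains("AMKA", lib)
  expect_setequal(both$domain, c("m1", "m2"))

  rep_lib <- data.frame(name = "rr", motif = "AA")
  expect_equal(identify_domains("AAA", rep_lib)$position, c(0L, 1L))

  expect_error(identify_domains("AB1", lib), "invalid amino-acid")
})

test_that("ORF similarity is the genomic Jaccard of CDS footprints", {
  cds300 <- test_cds(99)   # 3 + 98*3 + 3 = 300 nt
  m1 <- single_exon_model("t1", cds300)
  orf1 <- find_orf(cds300)
  expect_equal(orf_similarity(m1, m1, orf1, orf1), 1.0)

  m2 <- single_exon_model("t2", cds300, origin = 1000)
  expect_equal(orf_similarity(m1, m2, orf1, orf1), 0.0)
  expect_equal(orf_similarity(m1, m2, orf1, NULL), 0.0)

  # offset single-exon CDS: [0,300) vs [150,450) -> 150/450
  m3 <- single_exon_model("t3", cds300, origin = 150)
  expect_equal(orf_similarity(m1, m3, orf1, orf1), 1 / 3)
})

test_that("pair classification fills every axis from the event orientation", {
  # coding -> noncoding with domain loss
  lib <- sim_domain_library()
  motif_cds <- paste0("ATG",
                      paste(rep("GAA", 20), collapse = ""),
                      "TGTTGGCATTGTTGGCATTGT",   # CWHCWHC
                      paste(rep("GAA", 80), collapse = ""), "TAA")
  coding <- single_exon_model("cod", motif_cds, gene = "g")
  noncod <- single_exon_model("non", strrep("CCA", 60), gene = "g",
                              origin = 5000)
  rec <- classify_pair(list(iso_before = "cod", iso_after = "non"),
                       list(cod = coding, non = noncod), lib = lib)
  expect_equal(rec$cp_class, "coding->noncoding")
  expect_equal(rec$orf_class, "complete loss")
  expect_equal(rec$domains_lost[[1]], "zf_like")
  expect_equal(length(rec$domains_gained[[1]]), 0)
  expect_equal(rec$orf_similarity, 0)

  # identical ORFs: similar on every axis
  twin <- single_exon_model("twin", motif_cds, gene = "g")
  rec2 <- classify_pair(list(iso_before = "cod", iso_after = "twin"),
                        list(cod = coding, twin = twin), lib = lib)
  expect_equal(rec2$orf_class, "similar")
  expect_equal(rec2$nmd_class, "unchanged")
  expect_equal(rec2$ir_class, "unchanged")
  expect_equal(rec2$orf_similarity, 1.0)

  # ORF lengths 300 vs 360: relative difference 0.167 -> longer
  m300 <- single_exon_model("s", test_cds(99), gene = "g")
  m360 <- single_exon_model("l", test_cds(119), gene = "g")
  rec3 <- classify_pair(list(iso_before = "s", iso_after = "l"),
                        list(s = m300, l = m360))
  expect_equal(rec3$orf_class, "longer")

  # missing model is a recorded skip, not an error
  expect_null(classify_pair(list(iso_before = "s", iso_after = "gone"),
                            list(s = m300)))
  ev <- data.frame(gene_id = "g", iso_before = "s", iso_after = "gone")
  res <- classify_switches(ev, list(s = m300))
  expect_equal(nrow(res), 0)
  expect_match(attr(res, "skipped"), "gone")
})

test_that("STP summaries use the exact binomial on gains vs losses", {
  rec <- function(cp) data.frame(
    cp_class = cp, orf_class = "similar", nmd_class = "unchanged",
    ir_class = "unchanged",
    domains_gained = I(list(character(0))),
    domains_lost = I(list(character(0))))
  nine_one <- do.call(rbind, c(rep(list(rec("noncoding->coding")), 9),
                               list(rec("coding->noncoding"))))
  s <- summarize_consequences(nine_one)
  cp_row <- s[s$axis == "cp", ]
  expect_identical(cp_row$p, 0.021484375)
  expect_true(cp_row$ci_low > 0.5)

  even <- do.call(rbind, c(rep(list(rec("noncoding->coding")), 5),
                           rep(list(rec("coding->noncoding")), 5)))
  expect_equal(summarize_consequences(even)[1, "p"], 1.0)

  flat <- do.call(rbind, rep(list(rec("coding->coding")), 4))
  expect_true(is.na(summarize_consequences(flat)[1, "p"]))
})

test_that("binomial p matches exhaustive enumeration for all n <= 12", {
  # oracle: two-sided exact test as the total mass of outcomes no more
  # probable than the observed one
  enum_p <- function(g, n) {
    probs <- dbinom(0:n, n, 0.5)
    sum(probs[probs <= dbinom(g, n, 0.5) * (1 + 1e-7)])
  }
  rec <- function(cp) data.frame(
    cp_class = cp, orf_class = "similar", nmd_class = "unchanged",
    ir_class = "unchanged", domains_gained = I(list(character(0))),
    domains_lost = I(list(character(0))))
  for (n in 1:12) {
    for (g in 0:n) {
      records <- do.call(rbind, c(
        rep(list(rec("noncoding->coding")), g),
        rep(list(rec("coding->noncoding")), n - g)))
      got <- summarize_consequences(records)[1, "p"]
      expect_equal(got, enum_p(g, n), tolerance = 1e-12)
    }
  }
})
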
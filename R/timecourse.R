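#' Read a Salmon-style quantification table
#'
#' Parses a per-sample transcript quantification table in the `quant.sf`
#' dialect: a tab-separated file whose header contains the columns
#' `Name`, `Length`, `EffectiveLength`, `TPM` and `NumReads` (in any order;
#' extra columns are ignored).
#'
#' @param path Path to a tab-separated quantification file.
#' @return A `data.frame` with columns `transcript_id`, `length`,
#'   `effective_length`, `tpm`, `num_reads`; zero rows for a header-only file.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) {
    stop("quantification file not found: ", path)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("quantification table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(
    transcript_id    = as.character(tab[["Name"]]),
    length           = as.integer(tab[["Length"]]),
    effective_length = as.numeric(tab[["EffectiveLength"]]),
    tpm              = as.numeric(tab[["TPM"]]),
    num_reads        = as.numeric(tab[["NumReads"]]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$transcript_id)) {
    stop("duplicate transcript_id in ", path, ": ",
         out$transcript_id[duplicated(out$transcript_id)][1L])
  }
  bad <- which(!is.finite(out$tpm) | out$tpm < 0)
  if (length(bad)) {
    # +1 for the header line
    stop("negative or non-finite TPM in ", path, " at line ", bad[1L] + 1L)
  }
  bad <- which(!is.finite(out$num_reads) | out$num_reads < 0)
  if (length(bad)) {
    stop("negative or non-finite NumReads in ", path, " at line ", bad[1L] + 1L)
  }
  out
}

#' Read a transcript-to-gene mapping
#'
#' Two-column tab-separated file (`transcript_id`, `gene_id`). A header line
#' is detected and skipped when the second field matches `gene` (case
#' insensitive).
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping transcript ids to gene ids.
#' @export
read_tx2gene <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("tx2gene file must have two columns: ", path)
  if (nrow(tab) && grepl("gene", tab[1L, 2L], ignore.case = TRUE) &&
      grepl("transcript|tx", tab[1L, 1L], ignore.case = TRUE)) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (anyDuplicated(tab[[1L]])) {
    stop("duplicate transcript_id in tx2gene: ",
         tab[[1L]][duplicated(tab[[1L]])][1L])
  }
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Construct a time-course TPM matrix
#'
#' The central container of the pipeline: a transcripts-by-times matrix of
#' TPM values with strictly increasing sampling times (hours) and a
#' transcript-to-gene map covering every row.
#'
#' @param values Numeric matrix, rows = transcripts (rownames required),
#'   columns = time points.
#' @param times Numeric vector of sampling times in hours, strictly
#'   increasing, one per column.
#' @param tx2gene Named character vector mapping every rowname to a gene id.
#' @return An object of class `time_course_matrix`.
#' @export
time_course_matrix <- function(values, times, tx2gene) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have transcript rownames")
  if (length(times) != ncol(values)) {
    stop("length(times) must equal ncol(values)")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (anyDuplicated(rownames(values))) stop("duplicate transcript ids")
  unmapped <- setdiff(rownames(values), names(tx2gene))
  if (length(unmapped)) {
    stop("transcript(s) lacking a gene mapping: ",
         paste(utils::head(unmapped, 3), collapse = ", "))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("TPM values must be finite and non-negative")
  }
  colnames(values) <- paste0("t", format(times, trim = TRUE, scientific = FALSE))
  structure(
    list(values = values, times = as.numeric(times),
         tx2gene = tx2gene[rownames(values)]),
    class = "time_course_matrix"
  )
}

#' @export
print.time_course_matrix <- function(x, ...) {
  cat("time_course_matrix:", nrow(x$values), "transcripts x",
      length(x$times), "time points\n")
  cat("  times (h):", paste(x$times, collapse = ", "), "\n")
  cat("  genes:", length(unique(x$tx2gene)), "\n")
  invisible(x)
}

#' Assemble per-timepoint quantifications into a time-course matrix
#'
#' Columns are sorted by sampling time. By default every table must contain
#' the identical transcript set: a transcript present in one sample and
#' absent in another aborts assembly, because silently zero-filling can
#' fabricate expression switches. With `fill_missing = TRUE` the union of
#' transcripts is used and absent entries are set to 0.
#'
#' @param tables List of quantification `data.frame`s as returned by
#'   [read_quant_table()].
#' @param times Numeric vector of sampling times (hours), one per table;
#'   must be distinct.
#' @param tx2gene Named character vector (transcript id to gene id).
#' @param fill_missing Zero-fill transcripts absent from some samples.
#' @param strip_versions Strip trailing `.N` version suffixes from
#'   transcript ids (in both tables and the map) before matching.
#' @return A [time_course_matrix()].
#' @export
assemble_time_course <- function(tables, times, tx2gene,
                                 fill_missing = FALSE,
                                 strip_versions = FALSE) {
  if (length(tables) < 2) stop("need at least 2 samples")
  if (length(times) != length(tables)) {
    stop("one sampling time per table required")
  }
  if (anyDuplicated(times)) stop("duplicate sampling time: ",
                                 times[duplicated(times)][1L])
  ord <- order(times)
  tables <- tables[ord]
  times <- times[ord]
  if (strip_versions) {
    tables <- lapply(tables, function(t) {
      t$transcript_id <- strip_tx_version(t$transcript_id); t
    })
    names(tx2gene) <- strip_tx_version(names(tx2gene))
  }
  ids <- lapply(tables, `[[`, "transcript_id")
  all_ids <- unique(unlist(ids))
  if (!fill_missing) {
    for (i in seq_along(ids)) {
      absent <- setdiff(all_ids, ids[[i]])
      if (length(absent)) {
        stop("transcript ", absent[1L], " absent from sample at time ",
             times[i], " h (use fill_missing = TRUE to zero-fill)")
      }
    }
  }
  values <- matrix(0, nrow = length(all_ids), ncol = length(tables),
                   dimnames = list(all_ids, NULL))
  for (i in seq_along(tables)) {
    values[tables[[i]]$transcript_id, i] <- tables[[i]]$tpm
  }
  time_course_matrix(values, times, tx2gene)
}

strip_tx_version <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Write / read a time-course matrix as TSV
#'
#' The dialect is one row per transcript with a `transcript_id` column
#' followed by one column per time point named `t<hours>`. Values are
#' written with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param x A [time_course_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(x, path) {
  stopifnot(inherits(x, "time_course_matrix"))
  header <- c("transcript_id", colnames(x$values))
  lines <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(rownames(x$values)[i],
            sprintf("%.17g", x$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), lines), path)
  invisible(path)
}

#' @param tx2gene Named character vector used to rebuild the gene map.
#' @rdname write_time_course
#' @export
read_time_course <- function(path, tx2gene) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  tcols <- grep("^t[0-9]", names(tab), value = TRUE)
  times <- as.numeric(sub("^t", "", tcols))
  values <- as.matrix(tab[, tcols, drop = FALSE])
  rownames(values) <- tab$transcript_id
  time_course_matrix(values, times, tx2gene)
}

#' Read a domain-motif library
#'
#' Tab-separated file with a header naming a domain column (`name` or
#' `domain`) and a motif column (`motif` or `pattern`). Motifs are stored
#' verbatim and interpreted as regular expressions over the amino-acid
#' alphabet by [identify_domains()].
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `name` and `motif`.
#' @export
read_domain_library <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  ncol_name <- intersect(c("name", "domain", "domain_name"), names(tab))[1L]
  ncol_motif <- intersect(c("motif", "pattern"), names(tab))[1L]
  if (is.na(ncol_name) || is.na(ncol_motif)) {
    stop("domain library needs name/domain and motif/pattern columns: ", path)
  }
  out <- data.frame(name = tab[[ncol_name]], motif = tab[[ncol_motif]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$name)) {
    stop("duplicate domain name: ", out$name[duplicated(out$name)][1L])
  }
  empty <- which(!nzchar(out$motif))
  if (length(empty)) stop("empty motif at line ", empty[1L] + 1L)
  out
}

#' Read a GMT gene-set collection
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated.
#'
#' @param path Path to the GMT file.
#' @return A list with elements `sets` (named list of member character
#'   vectors), `descriptions` (named character) and `universe` (`NULL`;
#'   filled by the caller if an explicit background is available).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descriptions <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has no members")
    }
    id <- fields[1L]
    if (id %in% names(sets)) stop("duplicate set_id: ", id)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, " has no members")
    sets[[id]] <- members
    descriptions[[id]] <- fields[2L]
  }
  list(sets = sets, descriptions = descriptions, universe = NULL)
}

#' Write a GMT gene-set collection
#'
#' @param collection A list as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    desc <- collection$descriptions[[id]]
    if (is.null(desc) || is.na(desc)) desc <- ""
    paste(c(id, desc, collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
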
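#' Read a gene-by-sample expression matrix
#'
#' Reads tab-delimited expression text: either a plain TSV whose header row
#' holds sample identifiers and whose first column holds gene identifiers,
#' or the two-header-line GCT dialect (version line, dimension line, and a
#' `Description` column that is dropped).  Values can be in any monotone
#' normalization (RPKM, microarray intensities, ...): downstream estimators
#' only use ranks.
#'
#' Duplicate gene rows are resolved by keeping the highest-variance row
#' (rank estimators need informative profiles).  Zero-variance genes are
#' retained but flagged in the `zero_variance` attribute, since they are
#' uninformative to rank-based estimators.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the GCT version line), `"tsv"` or `"gct"`.
#' @return numeric matrix (genes x samples) with dimnames; attribute
#'   `zero_variance` holds the flagged gene ids.  A warning of class
#'   `cindy_small_n` is raised when fewer than 150 samples are present
#'   (inference is unreliable below that).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  if (format == "auto")
    format <- if (length(lines) && startsWith(lines[[1]], "#1.")) "gct" else "tsv"
  drop_desc <- FALSE
  if (format == "gct") {
    if (length(lines) < 3) abort("malformed GCT: fewer than 3 lines")
    lines <- lines[-c(1, 2)]
    drop_desc <- TRUE
  }
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- header[-1]
  if (drop_desc) samples <- samples[-1]
  if (anyDuplicated(samples))
    abort(paste0("duplicate sample ids: ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  rows <- fields[-1]
  genes <- vapply(rows, `[[`, "", 1L)
  vals <- matrix(NA_real_, length(rows), length(samples))
  for (i in seq_along(rows)) {
    f <- rows[[i]][-1]
    if (drop_desc) f <- f[-1]
    if (length(f) != length(samples))
      abort(sprintf("row '%s' has %d values, expected %d",
                    genes[i], length(f), length(samples)))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(sprintf("malformed numeric cell at gene '%s', sample '%s': '%s'",
                    genes[i], samples[j], f[j]))
    }
    vals[i, ] <- v
  }
  # duplicates: keep the highest-variance row
  if (anyDuplicated(genes)) {
    rv <- apply(vals, 1, var)
    keep <- tapply(seq_along(genes), genes, function(ix) ix[which.max(rv[ix])])
    keep <- sort(unlist(keep, use.names = FALSE))
    genes <- genes[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  dimnames(vals) <- list(genes, samples)
  if (ncol(vals) < 3) abort("expression matrix needs at least 3 samples")
  if (ncol(vals) < 150)
    warn(sprintf("only %d samples: modulator inference is recommended with at least 150",
                 ncol(vals)),
         class = "cindy_small_n")
  rv <- apply(vals, 1, var)
  attr(vals, "zero_variance") <- genes[rv == 0]
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the plain TSV dialect.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], format(mat[i, ], digits = 15, trim = TRUE,
                                     scientific = FALSE)),
          collapse = "\t"), "")
  writeLines(body, con)
  invisible(path)
}

#' Read a gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored;
#' duplicates are collapsed.
#'
#' @param path file path.
#' @param role one of `"modulator"`, `"transcription_factor"`, `"target"`.
#' @return character vector of unique ids with attribute `role`.
#' @export
read_gene_list <- function(path,
                           role = c("modulator", "transcription_factor", "target")) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- trimws(sub("#.*$", "", readLines(path)))
  x <- unique(x[nzchar(x)])
  if (!length(x)) abort(paste0("no gene identifiers in ", path))
  structure(x, role = role)
}

#' Read gold-standard modulator/TF interaction pairs
#'
#' Each file holds one tab-separated `(modulator, tf)` pair per line.  Pairs
#' are unioned across files, self-pairs (homodimerizations) dropped and
#' duplicates collapsed, keeping per-pair provenance labels.  Because the
#' generic PPI sources are undirected, the default also inserts the reversed
#' orientation of every pair so that matching against called `(M, TF)` pairs
#' ignores direction; set `symmetric = FALSE` for directed sources.
#'
#' @param paths character vector of pair-file paths.
#' @param symmetric insert the reverse of every pair (default `TRUE`).
#' @return tibble of class `gold_standard` with columns `m_id`, `tf_id`,
#'   `sources`.
#' @export
read_gold_standard <- function(paths, symmetric = TRUE) {
  all <- purrr::map_dfr(paths, function(p) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
    ln <- readLines(p)
    ln <- ln[nzchar(trimws(ln))]
    ln <- ln[!startsWith(trimws(ln), "#")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    bad <- which(lengths(f) != 2L)
    if (length(bad))
      abort(sprintf("%s line %d: expected 2 tab-separated columns, got %d",
                    p, bad[1], lengths(f)[bad[1]]))
    tibble(m_id = vapply(f, `[[`, "", 1L),
           tf_id = vapply(f, `[[`, "", 2L),
           source = basename(p))
  })
  all <- filter(all, .data$m_id != .data$tf_id)
  if (symmetric)
    all <- bind_rows(all, tibble(m_id = all$tf_id, tf_id = all$m_id,
                                 source = all$source))
  out <- all %>%
    group_by(.data$m_id, .data$tf_id) %>%
    summarise(sources = paste(sort(unique(.data$source)), collapse = ";"),
              .groups = "drop")
  class(out) <- c("gold_standard", class(out))
  out
}

write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_tsv <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              check.names = FALSE))
}

#' Writers/readers for result tables
#'
#' Round-trip safe TSV writers for the pair-level and triplet-level result
#' tables (`pairs.tsv` columns: `m_id, tf_id, n_sig, p, q, called`;
#' `triplets.tsv` columns: `m_id, tf_id, tg_id, mi, cmi, p, significant`).
#'
#' @param pairs,triplets result tibbles as produced by [call_modulations()]
#'   and [score_triplets()].
#' @param path file path.
#' @return the path (writers) or a tibble (readers).
#' @name result_io
NULL

#' @rdname result_io
#' @export
write_pairs <- function(pairs, path) write_table_tsv(pairs, path)

#' @rdname result_io
#' @export
read_pairs <- function(path) read_table_tsv(path)

#' @rdname result_io
#' @export
write_triplets <- function(triplets, path) write_table_tsv(triplets, path)

#' @rdname result_io
#' @export
read_triplets <- function(path) read_table_tsv(path)
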
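# Plain-text readers and writers for the formats the pipeline exchanges:
# word2vec text lexicons, story tables, delimited BOLD matrices with a
# manifest, atlas label tables, and tidy score/result tables.

#' Write an embedding lexicon in word2vec text format
#'
#' Header line \code{"<vocab_count> <dim>"}, then one line per token:
#' \code{"token v1 v2 ... vd"}.
#'
#' @param lexicon an \code{"embedding_lexicon"} (or token-named numeric
#'   matrix).
#' @param path output file.
#' @export
write_lexicon <- function(lexicon, path) {
  m <- as.matrix(lexicon)
  if (is.null(rownames(m))) stop("lexicon rows must be named", call. = FALSE)
  lines <- c(paste(nrow(m), ncol(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i],
                       formatC(m[i, ], format = "g", digits = 17)),
                     collapse = " "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an embedding lexicon from word2vec text format
#'
#' @param path file written by [write_lexicon()] or any word2vec-style text
#'   embedding file.
#' @return An \code{"embedding_lexicon"} matrix (cluster attribute
#'   reconstructed from synthetic \code{c<k>_w<i>} token names when all
#'   tokens follow that pattern).
#' @export
read_lexicon <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  header <- scan(con, what = integer(), n = 2L, quiet = TRUE)
  vocab <- header[1L]; d <- header[2L]
  toks <- character(vocab)
  vecs <- matrix(NA_real_, vocab, d)
  for (i in seq_len(vocab)) {
    fields <- scan(con, what = character(), n = d + 1L, quiet = TRUE)
    toks[i] <- fields[1L]
    vecs[i, ] <- as.numeric(fields[-1L])
  }
  rownames(vecs) <- toks
  cluster <- NULL
  if (all(grepl("^c[0-9]+_w[0-9]+$", toks)))
    cluster <- as.integer(sub("^c([0-9]+)_w[0-9]+$", "\\1", toks))
  structure(vecs, cluster = cluster, class = c("embedding_lexicon", "matrix"))
}

#' Write a story table as TSV
#'
#' @param stories data.frame with columns \code{id}, \code{condition},
#'   \code{text}.
#' @param path output file.
#' @export
write_stories <- function(stories, path) {
  stopifnot(all(c("id", "condition", "text") %in% names(stories)))
  utils::write.table(stories, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a story table from TSV
#'
#' @param path TSV with columns \code{id}, \code{condition}, \code{text}.
#' @return A data.frame.
#' @export
read_stories <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Write a synthetic BOLD set to a directory
#'
#' One delimited matrix file per subject/condition/trial (time points in
#' rows, regions in columns), a \code{manifest.tsv} (subject, condition,
#' trial, file, T) and an \code{atlas.tsv} (node_index, network_name).
#'
#' @param bold a \code{"bold_set"} from [make_bold()].
#' @param dir output directory (created if absent).
#' @export
write_bold <- function(bold, dir) {
  stopifnot(inherits(bold, "bold_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in seq_along(bold$series)) {
    for (cond in names(bold$series[[s]])) {
      trials <- bold$series[[s]][[cond]]
      for (tr in seq_along(trials)) {
        file <- sprintf("sub%02d_%s_trial%02d.tsv", s, cond, tr)
        m <- t(trials[[tr]]$mat)  # T rows x N columns
        utils::write.table(m, file.path(dir, file), sep = "\t",
                           quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s, condition = cond, trial = tr, file = file,
                     T = nrow(m), stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node_index = bold$atlas$node,
               network_name = bold$atlas$network),
    file.path(dir, "atlas.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Read a BOLD set from a manifest directory
#'
#' @param dir directory written by [write_bold()] (containing
#'   \code{manifest.tsv} and \code{atlas.tsv}).
#' @return A list with \code{series} (nested subject/condition/trial list of
#'   [region_ts()]) and \code{atlas} (data.frame).
#' @export
read_bold <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  atlas <- utils::read.delim(file.path(dir, "atlas.tsv"),
                             stringsAsFactors = FALSE)
  series <- list()
  for (r in seq_len(nrow(manifest))) {
    s <- manifest$subject[r]
    cond <- manifest$condition[r]
    tr <- manifest$trial[r]
    m <- as.matrix(utils::read.delim(file.path(dir, manifest$file[r]),
                                     header = FALSE))
    ts <- region_ts(t(m), atlas = atlas$network_name, subject = s,
                    condition = cond, trial = tr)
    if (length(series) < s) series[[s]] <- list()
    if (is.null(series[[s]][[cond]])) series[[s]][[cond]] <- list()
    series[[s]][[cond]][[tr]] <- ts
  }
  list(series = series, atlas = atlas)
}

#' Write per-story semantic scores as TSV
#'
#' @param scores data.frame with one row per story and metric, e.g. columns
#'   \code{id}, \code{condition}, \code{metric}, \code{value}, \code{n},
#'   \code{n_dropped}.
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a behavioral score table from TSV
#'
#' @param path TSV of numeric per-subject scores.
#' @return A data.frame.
#' @export
read_behavioral <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
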
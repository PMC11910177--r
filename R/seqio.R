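# Sequence input/output, cleaning, redundancy reduction and feature-table
# persistence. Sequences travel through the package as named character
# vectors (names = record ids, values = uppercase strings over {A,C,G,T}).

DNA_BASES <- c("A", "C", "G", "T")

#' Read DNA sequences from a FASTA file
#'
#' Parses a (possibly multi-line, mixed-case) FASTA file into a named
#' character vector of uppercase sequences. Record ids are taken from the
#' header line up to the first whitespace. No alphabet filtering happens
#' here: ambiguity codes survive parsing so that [clean_sequences()] (and
#' its policy) decides their fate.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are record ids, values uppercase
#'   residue strings.
#' @seealso [clean_sequences()], [write_fasta()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 some description", "acgt", ">g2", "TTGA", "CC"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop("FASTA record with empty sequence: ",
         paste(ids[widths == 0L], collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Remove sequences containing non-ACGT characters
#'
#' Sequence records containing any character outside `{A,C,G,T}` (ambiguity
#' codes such as N, gaps, ...) are removed (`policy = "drop"`, the default)
#' or trigger an error naming the offending record and 1-based offset
#' (`policy = "error"`). Input order is preserved and the number of removals
#' is reported with a message.
#'
#' @param seqs Named character vector of sequences.
#' @param policy `"drop"` or `"error"`.
#' @return Named character vector of clean sequences.
#' @export
clean_sequences <- function(seqs, policy = c("drop", "error")) {
  policy <- match.arg(policy)
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  bad <- grepl("[^ACGT]", seqs)
  if (policy == "error" && any(bad)) {
    first <- which(bad)[1L]
    off <- regexpr("[^ACGT]", seqs[first])
    stop(sprintf("invalid residue in record '%s' at position %d",
                 names(seqs)[first], as.integer(off)), call. = FALSE)
  }
  if (any(bad)) {
    message(sum(bad), " sequence(s) removed (non-ACGT characters)")
  }
  seqs[!bad]
}

# Multiset of overlapping k-mers of one sequence, as a named count table.
kmer_multiset <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  table(substring(seq, 1:(n - k + 1L), k:n))
}

# Estimated identity between two sequences: shared overlapping k-mers
# (multiset intersection) over the k-mer count of the shorter sequence.
kmer_identity <- function(a, b, k = 5L) {
  ta <- kmer_multiset(a, k)
  tb <- kmer_multiset(b, k)
  denom <- min(sum(ta), sum(tb))
  if (denom == 0L) return(0)
  shared <- intersect(names(ta), names(tb))
  if (length(shared) == 0L) return(0)
  sum(pmin(ta[shared], tb[shared])) / denom
}

#' Greedy redundancy reduction of a sequence set
#'
#' A CD-HIT-style greedy clusterer: sequences are visited longest-first and
#' each joins the first cluster whose representative (the cluster founder,
#' i.e. its longest member) has estimated identity at or above the
#' threshold; otherwise it founds a new cluster. Identity between two
#' sequences is estimated as the fraction of shared overlapping 5-mers
#' (multiset intersection) relative to the 5-mer count of the shorter
#' sequence -- a documented approximation of CD-HIT's short-word filter,
#' not a re-implementation of that program.
#'
#' @param seqs Named character vector of cleaned sequences.
#' @param identity_threshold Fraction in (0, 1]; e.g. 0.70 matches the
#'   preprocessing used for the driver/passenger benchmark.
#' @return Named character vector of cluster representatives, in input
#'   order.
#' @export
reduce_redundancy <- function(seqs, identity_threshold = 0.70) {
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) {
    stop("reduce_redundancy: empty sequence set", call. = FALSE)
  }
  if (!(identity_threshold > 0 && identity_threshold <= 1)) {
    stop("identity_threshold must lie in (0, 1]", call. = FALSE)
  }
  ord <- order(-nchar(seqs))         # stable: ties keep input order
  rep_idx <- integer(0)              # indices (into seqs) of representatives
  for (i in ord) {
    placed <- FALSE
    for (r in rep_idx) {
      if (kmer_identity(seqs[[i]], seqs[[r]]) >= identity_threshold) {
        placed <- TRUE
        break
      }
    }
    if (!placed) rep_idx <- c(rep_idx, i)
  }
  n_drop <- length(seqs) - length(rep_idx)
  if (n_drop > 0L) {
    message(n_drop, " redundant sequence(s) clustered away at threshold ",
            identity_threshold)
  }
  seqs[sort(rep_idx)]
}

#' Assemble a labeled two-class dataset
#'
#' Concatenates positive (driver, label 1) and negative (passenger,
#' label 0) sequence sets into a `labeled_dataset`. Ids must be unique;
#' in particular an id present in both groups is rejected.
#'
#' @param pos,neg Named character vectors of cleaned sequences.
#' @return A `labeled_dataset`: list with elements `sequences` (named
#'   character vector) and `labels` (integer vector of 1s then 0s).
#' @export
assemble_dataset <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  collide <- intersect(names(pos), names(neg))
  if (length(collide) > 0L) {
    stop("id(s) present in both groups: ",
         paste(utils::head(collide, 5L), collapse = ", "), call. = FALSE)
  }
  sequences <- c(pos, neg)
  if (anyDuplicated(names(sequences))) {
    stop("duplicate sequence ids within a group", call. = FALSE)
  }
  structure(
    list(sequences = sequences,
         labels = c(rep(1L, length(pos)), rep(0L, length(neg)))),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled DNA dataset:", length(x$sequences), "sequences (",
      sum(x$labels == 1L), "positive /", sum(x$labels == 0L), "negative )\n")
  cat("Length range:", min(nchar(x$sequences)), "-",
      max(nchar(x$sequences)), "nt\n")
  invisible(x)
}

#' Construct a feature table
#'
#' A `feature_table` holds the 522-coefficient encodings of a set of
#' sequences: an id per row, a numeric matrix with exactly 522 finite
#' columns, optional binary labels, and a `layout_tag` naming the feature
#' layout version (models refuse tables whose tag differs from the one
#' they were trained on).
#'
#' @param matrix Numeric matrix, one row per sequence, 522 columns.
#' @param ids Character vector of row ids.
#' @param labels Optional integer vector of 0/1 labels.
#' @param layout_tag Layout version string; defaults to the package layout.
#' @return A `feature_table` object.
#' @export
feature_table <- function(matrix, ids, labels = NULL,
                          layout_tag = FEATURE_LAYOUT_TAG) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != N_FEATURES) {
    stop("feature matrix must have exactly ", N_FEATURES, " columns, got ",
         ncol(matrix), call. = FALSE)
  }
  if (nrow(matrix) != length(ids)) {
    stop("row count does not match id count", call. = FALSE)
  }
  if (!all(is.finite(matrix))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(matrix) || !all(labels %in% c(0L, 1L))) {
      stop("labels must be a 0/1 vector parallel to the rows", call. = FALSE)
    }
  }
  colnames(matrix) <- feature_names()
  rownames(matrix) <- NULL
  structure(list(ids = as.character(ids), matrix = matrix, labels = labels,
                 layout_tag = layout_tag),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$matrix), "sequences x", ncol(x$matrix),
      "coefficients (layout ", x$layout_tag, ")\n", sep = " ")
  if (!is.null(x$labels)) {
    cat("Labels:", sum(x$labels == 1L), "positive /",
        sum(x$labels == 0L), "negative\n")
  } else {
    cat("Unlabeled\n")
  }
  invisible(x)
}

#' Write a feature table to CSV
#'
#' Columns are `id`, `f001` ... `f522` and, when labels are present,
#' `label`. The layout tag is stored in a leading `#` comment line so the
#' file round-trips losslessly through [read_feature_table()].
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(id = table$ids, table$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$labels)) df$label <- table$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# layout_tag: ", table$layout_tag), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    stop("feature table not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  tag <- if (startsWith(first, "# layout_tag: ")) {
    sub("^# layout_tag: ", "", first)
  } else {
    FEATURE_LAYOUT_TAG
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  want <- feature_names()
  has_label <- "label" %in% names(df)
  expect_cols <- c("id", want, if (has_label) "label")
  if (!identical(names(df), expect_cols)) {
    stop("malformed feature CSV: expected columns id, f001..f",
         N_FEATURES, if (has_label) ", label", call. = FALSE)
  }
  mat <- as.matrix(df[, want])
  if (!is.numeric(mat)) {
    stop("malformed feature CSV: non-numeric feature cells", call. = FALSE)
  }
  feature_table(mat, ids = df$id,
                labels = if (has_label) df$label else NULL,
                layout_tag = tag)
}
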
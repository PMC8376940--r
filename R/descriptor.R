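#' Logistic normalization of a PSSM
#'
#' Maps every raw log-odds score through the logistic function
#' s(x) = 1 / (1 + exp(-x)), squashing the unbounded integer scores into
#' (0, 1) while preserving their order. This conditions the profile before
#' the cross-product summary so that no single extreme score dominates.
#'
#' @param pssm a [new_pssm()] object (or bare numeric matrix).
#' @return A numeric matrix of the same shape with entries in (0, 1).
#' @examples
#' normalize_pssm(new_pssm(matrix(0L, 2, 20), "p"))[1, 1]  # 0.5
#' @export
normalize_pssm <- function(pssm) {
  x <- unclass(pssm)
  attributes(x) <- attributes(x)["dim"]
  1 / (1 + exp(-x))
}

#' Fixed-length evolutionary descriptor of a PSSM
#'
#' Collapses a variable-length T x 20 profile into the 400-dimensional
#' vector that the OLPP embedding consumes: the normalized cross-product
#' matrix F = P'^T P' / T of the logistic-normalized profile P', flattened
#' row-major. F\[j, k\] is the mean over residues of s(x_ij) * s(x_ik), so
#' the descriptor captures how strongly each pair of amino-acid columns
#' co-varies along the sequence and is invariant to sequence length
#' (duplicating every row leaves it unchanged).
#'
#' @param pssm a [new_pssm()] object.
#' @return Named numeric vector of length 400 with entries in (0, 1\];
#'   attribute `protein_id` carries the source id.
#' @examples
#' d <- pssm_descriptor(new_pssm(matrix(0L, 5, 20), "p"))
#' all(d == 0.25)
#' @export
pssm_descriptor <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  if (nrow(pssm) < 1L) stop("PSSM has no rows")
  s <- normalize_pssm(pssm)
  f <- crossprod(s) / nrow(s)
  # row-major flatten (F is symmetric, but fix the convention regardless)
  v <- as.vector(t(f))
  names(v) <- paste0(
    rep(attr(pssm, "column_order"), each = 20L),
    rep(attr(pssm, "column_order"), times = 20L)
  )
  attr(v, "protein_id") <- attr(pssm, "protein_id")
  v
}

#' Descriptor matrix for a directory of PSSM files
#'
#' @param pssm_dir directory containing one PSSM per protein, either
#'   ASCII PSI-BLAST files (`.pssm`) or TSVs written by
#'   [write_pssm_tsv()] (`.tsv`).
#' @param ids optional character vector restricting (and ordering) the
#'   proteins; defaults to every file found.
#' @return Numeric matrix, one row per protein (rownames = protein ids),
#'   400 columns.
#' @export
descriptors_from_dir <- function(pssm_dir, ids = NULL) {
  files <- list.files(pssm_dir, pattern = "\\.(pssm|tsv)$", full.names = TRUE)
  have <- tools::file_path_sans_ext(basename(files))
  if (is.null(ids)) ids <- have
  missing <- setdiff(ids, have)
  if (length(missing) > 0L) {
    stop("no PSSM file for protein id(s): ", paste(missing, collapse = ", "))
  }
  rows <- lapply(ids, function(id) {
    f <- files[match(id, have)]
    p <- if (grepl("\\.tsv$", f)) read_pssm_tsv(f, id) else parse_ascii_pssm(f, id)
    pssm_descriptor(p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

#' Read a labeled protein-pair list
#'
#' @param path TSV with three columns: first protein id, second protein
#'   id, and an interaction label (1 = interacting, 0 = non-interacting).
#'   A header row is detected automatically.
#' @return Data frame with columns `id_a`, `id_b`, `label`.
#' @export
read_pairs <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             colClasses = "character")
  header <- suppressWarnings(is.na(as.numeric(first[[3L]])))
  df <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(df) < 3L) stop("pair list must have three columns")
  df <- df[, 1:3]
  names(df) <- c("id_a", "id_b", "label")
  df$label <- as.integer(df$label)
  if (!all(df$label %in% c(0L, 1L))) stop("pair labels must be 0 or 1")
  df
}

#' Write a labeled protein-pair list as TSV
#'
#' @param pairs data frame with columns `id_a`, `id_b`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-pair feature vectors from per-protein embeddings
#'
#' Represents the pair (A, B) as the concatenation of the two proteins'
#' embedded vectors, in that order; labels are carried through when
#' present.
#'
#' @param embeddings numeric matrix of per-protein embeddings with protein
#'   ids as rownames (d columns).
#' @param pairs data frame with columns `id_a`, `id_b` and optionally
#'   `label`.
#' @return List with `x` (n_pairs x 2d feature matrix) and `label`
#'   (integer vector, or NULL when absent).
#' @export
make_pair_features <- function(embeddings, pairs) {
  embeddings <- as.matrix(embeddings)
  ids <- rownames(embeddings)
  if (is.null(ids)) stop("'embeddings' must have protein ids as rownames")
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), ids)
  if (length(missing) > 0L) {
    stop("no embedding for protein id(s): ", paste(missing, collapse = ", "))
  }
  x <- cbind(embeddings[pairs$id_a, , drop = FALSE],
             embeddings[pairs$id_b, , drop = FALSE])
  rownames(x) <- paste(pairs$id_a, pairs$id_b, sep = "--")
  colnames(x) <- c(paste0("a", seq_len(ncol(embeddings))),
                   paste0("b", seq_len(ncol(embeddings))))
  list(x = x, label = if ("label" %in% names(pairs)) as.integer(pairs$label) else NULL)
}
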
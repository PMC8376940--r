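AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a position-specific scoring matrix (PSSM) object
#'
#' A PSSM is the per-residue substitution-score profile emitted by
#' iterative profile search (PSI-BLAST): one row per residue of the source
#' sequence, one column per standard amino acid, each entry the log-odds
#' score of that residue mutating to that amino acid.
#'
#' @param scores numeric matrix, T rows (residues) by 20 columns.
#' @param protein_id identifier of the source protein.
#' @param column_order the 20 amino-acid letters in column order.
#' @return An object of class `pssm`: the score matrix with attributes
#'   `protein_id` and `column_order`.
#' @examples
#' p <- new_pssm(matrix(0L, 3, 20), "toy")
#' dim(p)
#' @export
new_pssm <- function(scores, protein_id, column_order = AA_LETTERS) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    stop("a PSSM must have exactly 20 columns, got ", ncol(scores))
  }
  if (nrow(scores) < 1L) {
    stop("a PSSM must have at least one row")
  }
  if (!is.character(protein_id) || length(protein_id) != 1L || !nzchar(protein_id)) {
    stop("'protein_id' must be a single non-empty string")
  }
  if (length(column_order) != 20L) {
    stop("'column_order' must list 20 amino-acid letters")
  }
  storage.mode(scores) <- if (all(scores == round(scores))) "integer" else "double"
  dimnames(scores) <- list(NULL, column_order)
  structure(scores, protein_id = protein_id, column_order = column_order,
            class = c("pssm", class(scores)))
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM for '%s': %d residues x 20 amino acids\n",
              attr(x, "protein_id"), nrow(x)))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses with Biostrings after a structural pre-scan so that malformed
#' records are reported with their line number. Sequences are upper-cased
#' and whitespace-stripped; the non-standard letters X, B and Z are
#' accepted.
#'
#' @param path path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`, one row per
#'   record, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0L) stop("FASTA parse error at line 1: empty file")
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    stop("FASTA parse error at line 1: no '>' header found")
  }
  if (meaningful[1L] < headers[1L]) {
    stop("FASTA parse error at line ", meaningful[1L],
         ": sequence data before first header")
  }
  bounds <- c(headers, length(lines) + 1L)
  for (k in seq_along(headers)) {
    h <- headers[k]
    id <- trimws(sub("^>", "", lines[h]))
    id <- sub("\\s.*$", "", id)
    if (!nzchar(id)) {
      stop("FASTA parse error at line ", h, ": empty record header")
    }
    body <- lines[seq.int(h + 1L, length.out = bounds[k + 1L] - h - 1L)]
    if (!any(nzchar(gsub("\\s", "", body)))) {
      stop("FASTA parse error at line ", h, ": record '", id,
           "' has an empty sequence body")
    }
  }
  seqs <- Biostrings::readBStringSet(path)
  data.frame(
    id = sub("\\s.*$", "", names(seqs)),
    sequence = toupper(gsub("\\s", "", as.character(seqs))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write sequences to a FASTA file
#'
#' @param records data frame with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue carrying (at least) 20 integer substitution-score columns --
#' the full dialect carries 40 numeric columns of which the last 20 are
#' weighted-percentage columns -- then trailing statistics lines. Only the
#' first 20 score columns are kept, matching the T x 20 score-matrix
#' representation of a profile.
#'
#' @param path path to an ASCII PSSM file.
#' @param protein_id identifier for the resulting PSSM; defaults to the
#'   file name without extension.
#' @return A [new_pssm()] object with one row per residue.
#' @export
parse_ascii_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(protein_id)) {
    protein_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  letters20 <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    fields <- strsplit(ln, "\\s+")[[1L]]
    # residue rows start with an index and a single residue letter
    if (length(fields) >= 3L &&
        grepl("^[0-9]+$", fields[1L]) &&
        grepl("^[A-Za-z*]$", fields[2L])) {
      nums <- suppressWarnings(as.numeric(fields[-(1:2)]))
      nums <- nums[!is.na(nums)]
      # the full dialect carries 20 scores + 20 percentages (+ 2 trailing
      # per-position statistics); a bare score block carries 20
      if (!(length(nums) %in% c(20L, 40L, 42L))) {
        stop("PSSM parse error at line ", i, ": expected 20 or 40 numeric ",
             "score fields, found ", length(nums))
      }
      rows[[length(rows) + 1L]] <- nums[1:20]
    } else if (is.null(letters20) && length(fields) >= 20L &&
               all(grepl("^[A-Za-z]$", fields[1:20]))) {
      letters20 <- fields[1:20]
    }
  }
  if (length(rows) == 0L) {
    stop("PSSM parse error: no residue score rows found in ", path)
  }
  scores <- do.call(rbind, rows)
  if (is.null(letters20)) letters20 <- AA_LETTERS
  new_pssm(scores, protein_id, column_order = letters20)
}

#' Write a PSSM in the PSI-BLAST ASCII layout
#'
#' Emits a file re-readable by [parse_ascii_pssm()]: a header, a column
#' legend, one row per residue with 40 numeric columns (the 20 scores
#' followed by 20 zero placeholder percentages), and trailing statistics
#' lines. Used by the synthetic-data generator to produce
#' parser-exercising fixtures.
#'
#' @param pssm a [new_pssm()] object.
#' @param path output path.
#' @param residues optional character vector of residue letters, one per
#'   row; defaults to "A".
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(pssm, path, residues = NULL) {
  stopifnot(inherits(pssm, "pssm"))
  ord <- attr(pssm, "column_order")
  n <- nrow(pssm)
  if (is.null(residues)) residues <- rep("A", n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "Last position-specific scoring matrix computed"), con)
  writeLines(paste0("            ", paste(sprintf("%3s", c(ord, ord)), collapse = " ")), con)
  for (i in seq_len(n)) {
    writeLines(paste0(
      sprintf("%5d %s  ", i, residues[i]),
      paste(sprintf("%3d", as.integer(round(pssm[i, ]))), collapse = " "), "  ",
      paste(sprintf("%3d", rep(0L, 20L)), collapse = " ")
    ), con)
  }
  writeLines(c("", "                      K         Lambda", "Standard Ungapped    0.1347     0.3179"), con)
  invisible(path)
}

#' Write a PSSM as TSV
#'
#' Plain tab-separated layout: a header row with the 20 amino-acid
#' letters, then one row of scores per residue. Integer scores round-trip
#' losslessly through [read_pssm_tsv()]; non-integer scores are written at
#' full precision.
#'
#' @param pssm a [new_pssm()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pssm_tsv <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  df <- as.data.frame(unclass(pssm)[, , drop = FALSE])
  colnames(df) <- attr(pssm, "column_order")
  tryCatch(
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) {
      stop("cannot write PSSM TSV to '", path, "': ", conditionMessage(e))
    }
  )
  invisible(path)
}

#' Read a PSSM written by [write_pssm_tsv()]
#'
#' @param path path to the TSV file.
#' @param protein_id identifier for the PSSM; defaults to the file name.
#' @return A [new_pssm()] object.
#' @export
read_pssm_tsv <- function(path, protein_id = NULL) {
  if (is.null(protein_id)) {
    protein_id <- tools::file_path_sans_ext(basename(path))
  }
  df <- utils::read.delim(path, check.names = FALSE)
  new_pssm(as.matrix(df), protein_id, column_order = colnames(df))
}

#' Build (but do not run) a PSI-BLAST command line
#'
#' Constructs the `psiblast` invocation that would produce the ASCII PSSM
#' for one query sequence. Profile search against a large database
#' (e.g. SwissProt) is an external step; this package only assembles the
#' command and parses its output. Defaults follow the standard profile
#' protocol: e-value cutoff 0.001 and 3 iterations.
#'
#' @param seq_path FASTA file with the query sequence.
#' @param db_path BLAST database prefix.
#' @param evalue inclusion e-value threshold; must be positive.
#' @param iterations number of PSI-BLAST iterations; at least 1.
#' @param out_pssm path the ASCII PSSM should be written to.
#' @return The command as a single string.
#' @examples
#' psiblast_command("q.fasta", "swissprot", out_pssm = "q.pssm")
#' @export
psiblast_command <- function(seq_path, db_path, evalue = 0.001,
                             iterations = 3L, out_pssm = "query.pssm") {
  if (!is.numeric(evalue) || length(evalue) != 1L || evalue <= 0) {
    stop("'evalue' must be a positive number")
  }
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("'iterations' must be an integer >= 1")
  }
  paste(
    "psiblast",
    "-query", shQuote(seq_path),
    "-db", shQuote(db_path),
    "-evalue", format(evalue, scientific = FALSE, trim = TRUE),
    "-num_iterations", iterations,
    "-out_ascii_pssm", shQuote(out_pssm)
  )
}
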
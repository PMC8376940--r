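#' Specification of a synthetic PPI benchmark
#'
#' Describes a fully self-contained benchmark: random protein sequences,
#' PSSM-like profiles, and a labeled pair set whose class signal strength
#' is controlled by `effect`. With `effect = 0` the labels carry no
#' information (a null dataset); larger values shift both endpoints of
#' every interacting pair along a common latent direction, emulating the
#' correlated evolutionary signal that physically interacting proteins
#' accumulate, without claiming biological realism.
#'
#' @param n_proteins number of base proteins.
#' @param length_range (min, max) sequence length in residues; the
#'   minimum must be at least 50, mirroring the usual fragment filter.
#' @param n_pairs number of labeled pairs.
#' @param positive_fraction fraction of interacting pairs in (0, 1).
#' @param effect class-signal strength in units of the across-protein
#'   descriptor standard deviation.
#' @param noise_sd standard deviation of the i.i.d. descriptor noise
#'   added to every pair endpoint (descriptor entries are ~0.25 with
#'   across-protein spread ~0.02, so the default 0.01 is moderate noise).
#' @param seed integer seed; every downstream draw derives from it.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 100L, length_range = c(50L, 120L),
                       n_pairs = 400L, positive_fraction = 0.5,
                       effect = 1.0, noise_sd = 0.01, seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  n_pairs <- as.integer(n_pairs)
  length_range <- as.integer(length_range)
  if (n_proteins < 2L) stop("'n_proteins' must be >= 2")
  if (length(length_range) != 2L || length_range[1L] > length_range[2L]) {
    stop("'length_range' must be (min, max)")
  }
  if (length_range[1L] < 50L) {
    stop("'length_range' minimum must be >= 50 residues (fragment filter)")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("'positive_fraction' must be in (0, 1)")
  }
  if (n_pairs > n_proteins^2) {
    stop("'n_pairs' cannot exceed n_proteins^2")
  }
  if (round(positive_fraction * n_pairs) < 5) {
    stop("need at least 5 positive pairs (positive_fraction * n_pairs)")
  }
  if (effect < 0) stop("'effect' must be non-negative")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 n_pairs = n_pairs, positive_fraction = positive_fraction,
                 effect = effect, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate random protein sequences
#'
#' I.i.d. uniform draws over the 20 standard amino acids, lengths uniform
#' over the spec's range, fully determined by the spec seed.
#'
#' @param spec a [synth_spec()].
#' @return Data frame with columns `id` ("p001", ...) and `sequence`.
#' @export
synth_sequences <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    span <- spec$length_range[2L] - spec$length_range[1L] + 1L
    lens <- spec$length_range[1L] + sample.int(span, spec$n_proteins,
                                               replace = TRUE) - 1L
    data.frame(
      id = sprintf("p%03d", seq_len(spec$n_proteins)),
      sequence = vapply(lens, function(l) {
        paste(sample(AA_LETTERS, l, replace = TRUE), collapse = "")
      }, ""),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a PSSM-like profile for one sequence
#'
#' Integer scores emulating the shape of a real profile: each residue's
#' own amino-acid column gets a positive mode (around +5) and the other
#' columns draw from a centred discrete distribution on \[-5, 5\], so all
#' entries lie in \[-10, 10\]. The result round-trips through both the
#' ASCII and the TSV writers.
#'
#' @param record one-row data frame (or list) with `id` and `sequence`.
#' @param seed integer seed.
#' @return A [new_pssm()] object with T = nchar(sequence) rows.
#' @export
synth_pssm <- function(record, seed = 1L) {
  seq_chars <- strsplit(toupper(record$sequence), "")[[1L]]
  t_len <- length(seq_chars)
  with_seed(seed, {
    scores <- matrix(sample(-5:5, t_len * 20L, replace = TRUE), t_len, 20L)
    own <- match(seq_chars, AA_LETTERS)
    keep <- which(!is.na(own))  # non-standard letters keep background scores
    scores[cbind(keep, own[keep])] <- 5L + sample(-2:2, length(keep), replace = TRUE)
    new_pssm(scores, record$id)
  })
}

#' Generate a labeled synthetic pair dataset
#'
#' Builds the complete benchmark the pipeline trains on, with a
#' co-evolution-flavoured class signal. Every protein gets a base
#' descriptor from its synthetic profile. A dataset-level unit latent
#' direction is drawn inside the span of the five dominant principal
#' modes of the base descriptors (so the signature lives in the dominant
#' evolutionary covariation structure, which an unsupervised embedding
#' retains), and each protein carries a binary interface signature
#' z in \{+1, -1\}: its descriptor is shifted by
#' `effect` * sigma * z along the latent, where sigma is the standard
#' deviation of the base descriptors projected on the latent, plus
#' i.i.d. Gaussian noise (`noise_sd`).
#'
#' Labels couple to the signature through a noisy pair-level score:
#' s = `effect` * (+1 if both partners carry "+", else -1) + N(0, 1),
#' and exactly `positive_fraction * n_pairs` top-scoring pairs are
#' labeled interacting. At `effect = 0` the labels are therefore pure
#' pair-level noise (an exact null no classifier can exploit), while at
#' large `effect` they are almost fully determined by the two partners'
#' signatures -- information that is present, redundantly, in both
#' halves of the pair feature.
#'
#' @param spec a [synth_spec()].
#' @return List with `descriptors` (protein matrix, rownames = protein
#'   ids), `pairs` (data frame `id_a`, `id_b`, `label`), `proteins`
#'   (the base sequences), `base_descriptors`, `latent`, `signature`
#'   (the per-protein z), and `spec`.
#' @export
synth_pair_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  prot <- synth_sequences(spec)
  n_prot <- nrow(prot)
  base <- with_seed(spec$seed + 1L, {
    t(vapply(seq_len(n_prot), function(i) {
      pssm_descriptor(synth_pssm(prot[i, ], seed = spec$seed + 100L + i))
    }, numeric(400L)))
  })
  rownames(base) <- prot$id

  with_seed(spec$seed + 2L, {
    # latent interface direction in the span of the top descriptor modes
    n_modes <- min(5L, n_prot - 1L)
    pc <- stats::prcomp(base)
    co <- stats::rnorm(n_modes)
    latent <- as.numeric(pc$rotation[, seq_len(n_modes), drop = FALSE] %*%
                           (co / sqrt(sum(co^2))))
    sigma <- stats::sd(base %*% latent)

    # binary interface signature; P(+) = sqrt(positive_fraction) so that
    # both-plus pairs occur at roughly the requested positive rate
    n_plus <- max(1L, min(n_prot - 1L,
                          as.integer(round(n_prot * sqrt(spec$positive_fraction)))))
    z <- sample(rep(c(1, -1), c(n_plus, n_prot - n_plus)))
    desc <- base + outer(spec$effect * sigma * z, latent) +
      matrix(stats::rnorm(n_prot * 400L, 0, spec$noise_sd), n_prot, 400L)
    rownames(desc) <- prot$id

    # unique ordered pairs; labels from a noisy pair-level signature score
    pair_code <- sample.int(n_prot^2, spec$n_pairs)
    ia <- (pair_code - 1L) %/% n_prot + 1L
    ib <- (pair_code - 1L) %% n_prot + 1L
    both_plus <- z[ia] == 1 & z[ib] == 1
    score <- spec$effect * ifelse(both_plus, 1, -1) + stats::rnorm(spec$n_pairs)
    n_pos <- as.integer(round(spec$positive_fraction * spec$n_pairs))
    label <- integer(spec$n_pairs)
    label[order(score, decreasing = TRUE)[seq_len(n_pos)]] <- 1L

    list(
      descriptors = desc,
      pairs = data.frame(id_a = prot$id[ia], id_b = prot$id[ib],
                         label = label, stringsAsFactors = FALSE),
      proteins = prot,
      base_descriptors = base,
      latent = latent,
      signature = stats::setNames(z, prot$id),
      spec = spec
    )
  })
}

#' Write a synthetic benchmark to disk
#'
#' Emits the FASTA file, one ASCII PSSM-style file per protein, and the
#' labeled pairs TSV, so the on-disk pipeline entry points can be
#' exercised end to end.
#'
#' @param spec a [synth_spec()].
#' @param out_dir output directory (created if needed).
#' @return The dataset list from [synth_pair_dataset()], invisibly, with
#'   the file paths in `paths`.
#' @export
write_synth_fixtures <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- synth_pair_dataset(spec)
  fasta <- file.path(out_dir, "proteins.fasta")
  write_fasta(ds$proteins, fasta)
  pssm_dir <- file.path(out_dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(ds$proteins))) {
    p <- synth_pssm(ds$proteins[i, ], seed = spec$seed + 100L + i)
    write_ascii_pssm(p, file.path(pssm_dir, paste0(ds$proteins$id[i], ".pssm")),
                     residues = strsplit(ds$proteins$sequence[i], "")[[1L]])
  }
  pairs_path <- file.path(out_dir, "pairs.tsv")
  write_pairs(ds$pairs, pairs_path)
  ds$paths <- list(fasta = fasta, pssm_dir = pssm_dir, pairs = pairs_path)
  invisible(ds)
}
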
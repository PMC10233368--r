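#' Filter preference calls to candidate translocon substrates
#'
#' Secretory-pathway substrates must carry an ER-targeting element: a prey
#' is a substrate candidate iff it has a signal peptide (SP) or a
#' transmembrane domain (TMD), and no predicted mitochondrial targeting
#' signal (MTS) -- proteins with an MTS could be mitochondrial inner
#' membrane proteins rather than translocon clients.
#'
#' Preys without an annotation row are flagged (`annotation_missing`)
#' rather than silently dropped; their `candidate` status is `NA`.
#'
#' @param pairs Data frame of preference calls with at least `prey_id` and
#'   `category` (see [call_preferences()]).
#' @param annotations Data frame with columns `protein_id`, `has_sp`,
#'   `has_tmd`, `has_mts` (logical) and optionally `sp_sequence`.
#' @return `pairs` with added columns `has_sp`, `has_tmd`, `has_mts`,
#'   `candidate`, `annotation_missing`, plus an attribute
#'   `"category_counts"`: a table of candidate counts per preference
#'   category.
#' @export
filter_substrates <- function(pairs, annotations) {
  stopifnot(is.data.frame(pairs), is.data.frame(annotations))
  need <- c("protein_id", "has_sp", "has_tmd", "has_mts")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0L)
    stop("annotations table lacks column(s): ", paste(miss, collapse = ", "))
  idx <- match(pairs$prey_id, annotations$protein_id)
  out <- pairs
  out$has_sp <- as.logical(annotations$has_sp[idx])
  out$has_tmd <- as.logical(annotations$has_tmd[idx])
  out$has_mts <- as.logical(annotations$has_mts[idx])
  out$annotation_missing <- is.na(idx)
  out$candidate <- (out$has_sp | out$has_tmd) & !out$has_mts
  cand <- out[!is.na(out$candidate) & out$candidate, , drop = FALSE]
  attr(out, "category_counts") <- table(factor(cand$category,
                                               levels = preference_categories()))
  out
}

#' Per-position hydropathy profile of a group of signal peptides
#'
#' For each position `p` up to `max_len`, averages the Kyte-Doolittle
#' value of residue `p` over all sequences of length >= `p`.  This is the
#' per-amino-acid group average used to compare the N-terminal
#' hydrophobicity of SPs from preys preferring one translocon versus the
#' other; no sliding window is applied by default so that signals confined
#' to positions 1-3 remain sharp.  `window > 1` applies a centered moving
#' average to each sequence's hydropathy values before averaging.
#'
#' @param sequences Character vector of SP sequences (>= 1).
#' @param max_len Number of N-terminal positions profiled (default 25,
#'   covering typical SP lengths).
#' @param group Optional group label stored in the result.
#' @param window Odd integer smoothing window; 1 (default) disables
#'   smoothing.
#' @return Data frame with columns `group`, `position`, `mean_kd`,
#'   `sem_kd`, `n`.  `sem_kd` is the sample SD divided by `sqrt(n)`; for
#'   `n = 1` it is reported as 0 (the `n` column flags the convention).
#'   Positions no sequence reaches are omitted.
#' @export
group_profile <- function(sequences, max_len = 25L, group = "group",
                          window = 1L) {
  if (length(sequences) < 1L)
    stop("at least one sequence is required")
  if (window < 1L || window %% 2L == 0L)
    stop("'window' must be a positive odd integer")
  vals <- lapply(sequences, kd_values)
  if (window > 1L) {
    half <- (window - 1L) %/% 2L
    vals <- lapply(vals, function(v) {
      sapply(seq_along(v), function(i) {
        mean(v[max(1L, i - half):min(length(v), i + half)])
      })
    })
  }
  lens <- lengths(vals)
  pmax_ <- min(max_len, max(lens))
  rows <- lapply(seq_len(pmax_), function(p) {
    x <- unlist(lapply(vals[lens >= p], `[`, p))
    n <- length(x)
    if (n == 0L) return(NULL)
    data.frame(group = group, position = p, mean_kd = mean(x),
               sem_kd = if (n > 1L) stats::sd(x) / sqrt(n) else 0,
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exchange the N-terminal prefix of two signal peptides
#'
#' Swaps the first `k` residues between two sequences, producing the two
#' chimeric variants used to test whether the extreme N terminus carries
#' the translocon-preference information.  Applying the swap twice returns
#' the original sequences.
#'
#' @param seq1,seq2 Amino-acid strings.
#' @param k Number of N-terminal residues to exchange (default 3).
#' @return Named character vector `c(variant1=, variant2=)`: `variant1`
#'   carries the first `k` residues of `seq2` on the body of `seq1`, and
#'   vice versa.
#' @examples
#' swap_prefix("MKFAB", "MQRCD", 3)
#' @export
swap_prefix <- function(seq1, seq2, k = 3L) {
  stopifnot(is.character(seq1), is.character(seq2),
            length(seq1) == 1L, length(seq2) == 1L)
  k <- as.integer(k)
  if (k < 0L) stop("'k' must be >= 0")
  if (k > min(nchar(seq1), nchar(seq2)))
    stop(sprintf("k = %d exceeds a sequence length (%d, %d)",
                 k, nchar(seq1), nchar(seq2)))
  v1 <- paste0(substr(seq2, 1L, k), substr(seq1, k + 1L, nchar(seq1)))
  v2 <- paste0(substr(seq1, 1L, k), substr(seq2, k + 1L, nchar(seq2)))
  c(variant1 = v1, variant2 = v2)
}

#' Build a signal-peptide-only reporter construct record
#'
#' Models the validation construct in which only the SP of a protein is
#' fused to a fluorescent reporter body carrying an AviTag, so that the
#' reporter's biotinylation by a BirA-tagged translocon reads out the
#' preference conferred by the SP alone.
#'
#' @param sp SP amino-acid string (nonempty, standard residues).
#' @param donor_id Optional identifier of the protein donating the SP.
#' @param body Reporter body description (fixed tag metadata).
#' @return Object of class `sp_reporter`: list with `sp`, `donor_id`,
#'   `body`, and `construct` (the fused label).
#' @export
build_reporter <- function(sp, donor_id = NA_character_,
                           body = "mCherry-AviTag") {
  kd_values(sp)   # validates nonempty, standard residues
  structure(list(sp = sp, donor_id = donor_id, body = body,
                 construct = paste0(sp, "::", body)),
            class = "sp_reporter")
}

#' @export
print.sp_reporter <- function(x, ...) {
  cat("SP-only reporter construct\n")
  cat("  donor:", x$donor_id, "\n  SP   :", x$sp, "\n  body :", x$body, "\n")
  invisible(x)
}

#' Planted translocon preference of a signal peptide
#'
#' The toy mechanistic rule used by the synthetic screen: the preference a
#' SP confers is decided by the mean hydropathy of its first `k` residues
#' (hydrophobic N terminus -> bait A, hydrophilic -> bait B).  Under this
#' rule a reporter construct inherits the preference of its SP donor, and
#' a prefix-swapped SP inherits the preference of the prefix donor --
#' mirroring the domain-swap logic of the wet-lab validation.  It is a
#' deliberately simple stand-in for the real sequence determinants, used
#' only to give synthetic data a recoverable structure.
#'
#' @param sp SP amino-acid string (or an `sp_reporter`).
#' @param k Number of N-terminal residues considered (default 3).
#' @param cutoff Hydropathy cutoff (default 0).
#' @return `"prefers_A"` or `"prefers_B"`.
#' @export
sp_planted_preference <- function(sp, k = 3L, cutoff = 0) {
  if (inherits(sp, "sp_reporter")) sp <- sp$sp
  v <- kd_values(sp)
  if (length(v) < k) stop("sequence shorter than k")
  if (mean(v[seq_len(k)]) >= cutoff) "prefers_A" else "prefers_B"
}
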
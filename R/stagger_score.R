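# Discrete sliding-stagger interaction score between two collagen chains.
#
# Each ordered residue pair (i on seq1, j on seq2) whose aligned separation
# |i - (j + shift)| falls within the class window contributes: +1 for an
# opposite-charge pair or a hydrophobic pair, -1 for a like-charge pair,
# 0 otherwise. The score is scanned at every one-residue shift. A residue may
# participate in multiple pairs (pairs are counted independently).

#' Scoring parameters for the stagger scan
#'
#' @param charge_window half-width (residues) of the charged contact window
#'   (default 3).
#' @param hydrophobic_window half-width of the hydrophobic contact window
#'   (default 2).
#' @param gap_length unscored gap (residues) inserted after each molecule in
#'   periodic self-association scans (default 0; 156 mimics the natural
#'   Type I packing arrangement).
#' @param basic,acidic,hydrophobic residue sets. Defaults: K/R basic, D/E
#'   acidic, V/M/I/L/F/P hydrophobic.
#' @return a `score_params` list.
#' @export
score_params <- function(charge_window = 3L, hydrophobic_window = 2L,
                         gap_length = 0L,
                         basic = c("K", "R"), acidic = c("D", "E"),
                         hydrophobic = c("V", "M", "I", "L", "F", "P")) {
  stopifnot(charge_window >= 0, hydrophobic_window >= 0, gap_length >= 0)
  if (length(intersect(basic, acidic)) ||
      length(intersect(c(basic, acidic), hydrophobic))) {
    stop("residue classes must be disjoint")
  }
  structure(list(charge_window = as.integer(charge_window),
                 hydrophobic_window = as.integer(hydrophobic_window),
                 gap_length = as.integer(gap_length),
                 basic = basic, acidic = acidic, hydrophobic = hydrophobic),
            class = "score_params")
}

# residue class codes: 0 other/gap, 1 basic, 2 acidic, 3 hydrophobic
encode_residues <- function(seq, params, allow_gap = FALSE) {
  chars <- seq_chars(seq)
  std <- Biostrings::AA_STANDARD
  bad <- setdiff(unique(chars), c(std, if (allow_gap) "-"))
  if (length(bad)) {
    stop("non-standard amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  code <- integer(length(chars))
  code[chars %in% params$basic] <- 1L
  code[chars %in% params$acidic] <- 2L
  code[chars %in% params$hydrophobic] <- 3L
  code
}

#' Score a single residue pair
#'
#' @param a,b single amino-acid letters.
#' @param params a [score_params()] object.
#' @return +1 (opposite charges or both hydrophobic), -1 (like charges) or 0.
#' @export
pair_score <- function(a, b, params = score_params()) {
  ca <- encode_residues(a, params)
  cb <- encode_residues(b, params)
  if (ca %in% 1:2 && cb %in% 1:2) {
    if (ca == cb) -1L else 1L
  } else if (ca == 3L && cb == 3L) {
    1L
  } else 0L
}

new_score_profile <- function(shift, score, periodic = FALSE, repeat_length = NA) {
  structure(data.frame(shift = shift, score = score),
            class = c("score_profile", "data.frame"),
            periodic = periodic, repeat_length = repeat_length)
}

#' Scan the interaction score over all axial staggers
#'
#' Slides `seq2` along `seq1` one residue at a time; at shift `s` residue `j`
#' of `seq2` aligns at position `j + s` of `seq1`. The profile covers every
#' shift with at least notional overlap, from `-(len2 - 1)` to `len1 - 1`.
#'
#' @param seq1,seq2 residue strings (gap characters `-` score zero).
#' @param params a [score_params()] object.
#' @return a `score_profile` data.frame with integer columns `shift`, `score`.
#' @export
stagger_scan <- function(seq1, seq2, params = score_params()) {
  c1 <- encode_residues(seq1, params, allow_gap = TRUE)
  c2 <- encode_residues(seq2, params, allow_gap = TRUE)
  if (!length(c1) || !length(c2)) stop("sequences must be non-empty")
  score <- cpp_stagger_scan(c1, c2, params$charge_window, params$hydrophobic_window)
  new_score_profile(seq(-(length(c2) - 1L), length(c1) - 1L), score)
}

#' Periodic self-association scan with a lattice gap
#'
#' Mimics the packing of molecules arranged head-to-tail along a fiber axis
#' with an unscored gap after each molecule (156 residues, 0.6 D, for the
#' natural Type I arrangement): the sequence is scanned against a periodic
#' array of itself and the profile is reported over one axial repeat
#' (molecule length + gap).
#'
#' @param seq residue string.
#' @param params a [score_params()] with `gap_length` set; `gap_length = 0`
#'   reduces to [stagger_scan()] of the sequence against itself.
#' @return a `score_profile` over shifts `0 .. repeat_length - 1` (periodic),
#'   or the plain self-scan profile when `gap_length = 0`.
#' @export
scan_with_gap <- function(seq, params = score_params(gap_length = 156L)) {
  g <- params$gap_length
  if (g == 0L) return(stagger_scan(seq, seq, params))
  n <- nchar(seq)
  if (g >= n) stop("gap_length must be smaller than the sequence length")
  unit <- paste0(seq, strrep("-", g))
  array3 <- strrep(unit, 3L)
  prof <- stagger_scan(array3, seq, params)
  rep_len <- n + g
  keep <- prof$shift >= rep_len & prof$shift < 2L * rep_len
  new_score_profile(prof$shift[keep] - rep_len, prof$score[keep],
                    periodic = TRUE, repeat_length = rep_len)
}

#' Best-scoring staggers of a profile
#'
#' Orders shifts by descending score; ties broken toward smaller absolute
#' shift, then toward the positive shift.
#'
#' @param profile a `score_profile`.
#' @param k number of poses to return.
#' @return the top `k` rows of the profile in rank order.
#' @export
top_poses <- function(profile, k = 1L) {
  stopifnot(k >= 1L)
  if (k > nrow(profile)) stop("k exceeds the number of scanned shifts")
  ord <- order(-profile$score, abs(profile$shift), -sign(profile$shift))
  out <- profile[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("<score_profile> %d shifts (%d..%d), max score %d at shift %d\n",
              nrow(x), min(x$shift), max(x$shift), max(x$score),
              top_poses(x, 1L)$shift))
  invisible(x)
}
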
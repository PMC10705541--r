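DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' A PWM holds per-position base probabilities, a 0-order background model,
#' and a pseudocount fraction.  Scores are log2 odds against the background:
#' `score(b, i) = log2((p(b, i) + pseudocount * bg(b)) / bg(b))`, summed over
#' positions, so a uniform column under a uniform background scores 0 and a
#' deterministic match approaches 2 bits per position.
#'
#' @param name Motif name.
#' @param probs 4 x width numeric matrix (rows A, C, G, T); each column must
#'   sum to 1 within 1e-9.
#' @param background Length-4 probability vector over A, C, G, T.
#' @param pseudocount Small fraction of the background added to each
#'   probability before taking log odds (regularises zeros).
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, probs, background = rep(0.25, 4), pseudocount = 0.001) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) abort("`probs` must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 1) abort("PWM width must be >= 1")
  if (any(abs(colSums(probs) - 1) > 1e-9)) abort("every PWM column must sum to 1")
  background <- as.numeric(background)
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9) {
    abort("`background` must be 4 probabilities summing to 1")
  }
  rownames(probs) <- DNA_BASES
  structure(list(name = name, probs = probs,
                 background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  width %d  consensus %s\n",
              x$name, ncol(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per column)
#' @param x A `pwm`.
#' @return A character string.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 2, which.max)], collapse = "")
}

#' Build a PWM from an IUPAC consensus
#'
#' Each consensus letter distributes probability `1 - soft` equally over its
#' allowed bases and `soft` over the disallowed ones, giving a usable scoring
#' model for motifs published only as consensus strings.
#'
#' @param name Motif name.
#' @param consensus IUPAC string (A, C, G, T, R, Y, S, W, K, M, B, D, H, V, N).
#' @param soft Probability mass given to disallowed bases (default 0.04).
#' @inheritParams pwm
#' @return A `pwm`.
#' @export
pwm_from_consensus <- function(name, consensus, soft = 0.04,
                               background = rep(0.25, 4), pseudocount = 0.001) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = DNA_BASES)
  letters <- strsplit(toupper(consensus), "")[[1]]
  probs <- vapply(letters, function(ch) {
    allowed <- iupac[[ch]]
    if (is.null(allowed)) abort(sprintf("unknown IUPAC letter `%s`", ch))
    p <- rep(0, 4); names(p) <- DNA_BASES
    if (length(allowed) == 4) {
      p[] <- 0.25
    } else {
      p[allowed] <- (1 - soft) / length(allowed)
      p[setdiff(DNA_BASES, allowed)] <- soft / (4 - length(allowed))
    }
    p
  }, numeric(4))
  pwm(name, probs, background = background, pseudocount = pseudocount)
}

#' Log-odds score matrix of a PWM
#'
#' @param x A `pwm`.
#' @return A 4 x width matrix of log2-odds scores in bits.
#' @export
pwm_log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  log2((x$probs + x$pseudocount * x$background) / x$background)
}

#' Exact score distribution of a PWM under its background
#'
#' Computes, by dynamic programming over positions with scores discretised to
#' `granularity` bits, the exact distribution of the log-odds score of a
#' random background sequence, and from it the tail p-value
#' `P(score >= s)` used to threshold scan hits (the FIMO construction).
#'
#' @param x A `pwm`.
#' @param granularity Score discretisation in bits (default 1/1000 bit, small
#'   relative to any practical p-value threshold).
#' @return A list with `score` (ascending support, in bits), `prob`
#'   (summing to 1), `pvalue` (`P(score >= score[i])`), and `granularity`.
#' @export
pwm_score_distribution <- function(x, granularity = 0.001) {
  stopifnot(inherits(x, "pwm"))
  S <- round(pwm_log_odds(x) / granularity)  # integer scores, 4 x w
  w <- ncol(S)
  lo <- sum(apply(S, 2, min)); hi <- sum(apply(S, 2, max))
  probs <- numeric(hi - lo + 1)  # index k <-> integer score lo + k - 1
  # DP: start with position 1
  cur_lo <- 0
  cur <- 1  # P(empty prefix score == 0) = 1
  for (j in seq_len(w)) {
    nxt_lo <- cur_lo + min(S[, j])
    nxt_hi <- cur_lo + length(cur) - 1 + max(S[, j])
    nxt <- numeric(nxt_hi - nxt_lo + 1)
    for (b in 1:4) {
      sh <- cur_lo + S[b, j] - nxt_lo
      idx <- seq_along(cur) + sh
      nxt[idx] <- nxt[idx] + cur * x$background[b]
    }
    cur <- nxt
    cur_lo <- nxt_lo
  }
  keep <- cur > 0
  score_int <- (cur_lo + seq_along(cur) - 1)[keep]
  prob <- cur[keep]
  pvalue <- rev(cumsum(rev(prob)))
  list(score = score_int * granularity, score_int = score_int,
       prob = prob, pvalue = pvalue, granularity = granularity)
}

# Internal: tail p-values for integer (per-column discretised) scores.  The
# scores must come from the same rounded matrix the DP used, so every
# achievable score is an exact support atom.
score_pvalue_int <- function(dist, si) {
  idx <- findInterval(si - 1, dist$score_int) + 1
  p <- ifelse(idx > length(dist$score_int), 0,
              dist$pvalue[pmin(idx, length(dist$score_int))])
  as.numeric(p)
}

# Internal: tail p-values for raw bit scores (discretised here).
score_pvalue <- function(dist, scores) {
  score_pvalue_int(dist, round(scores / dist$granularity))
}

# Internal: DNA string -> integer codes (A=1 C=2 G=3 T=4, else NA).
seq_codes <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  match(v, DNA_BASES)
}

# Internal: sliding log-odds scores of every window of `codes` under matrix M.
window_scores <- function(codes, M) {
  w <- ncol(M)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n <- L - w + 1
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + M[cbind(codes[j:(j + n - 1)], j)]
  }
  sc
}

#' Scan sequences with a PWM at an exact p-value threshold
#'
#' Scores every window on both strands, converts scores to exact tail
#' p-values via [pwm_score_distribution()], and reports windows with
#' `p-value <= p_threshold`.  Windows containing non-ACGT letters are
#' skipped.  Reverse-strand hits are reported on the forward coordinate
#' frame.  When `background` is `NULL` the 0-order background is estimated
#' from the scanned sequences themselves (as FIMO does by default).
#'
#' @param x A `pwm` or a list of them.
#' @param sequences A named `DNAStringSet` or named character vector.
#' @param p_threshold Maximum hit p-value.
#' @param background Optional length-4 background probability override.
#' @return A tibble of hits: `motif`, `chrom` (sequence name), `start`, `end`
#'   (0-based half-open within the sequence), `strand`, `score` (bits),
#'   `pvalue`, `matched`.
#' @export
scan_motifs <- function(x, sequences, p_threshold = 1e-4, background = NULL) {
  if (inherits(x, "pwm")) x <- list(x)
  seqs <- if (inherits(sequences, "DNAStringSet")) as.character(sequences) else sequences
  if (!length(seqs)) {
    inform("scan_motifs: empty sequence set")
    return(empty_hits())
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("`sequences` must be named")
  }
  codes_list <- lapply(seqs, seq_codes)
  if (is.null(background)) {
    tab <- tabulate(unlist(codes_list, use.names = FALSE), nbins = 4)
    background <- if (sum(tab) > 0) tab / sum(tab) else rep(0.25, 4)
    if (any(background == 0)) background <- (tab + 1) / sum(tab + 1)
  }
  out <- list()
  for (p in x) {
    p_bg <- pwm(p$name, p$probs, background = background, pseudocount = p$pseudocount)
    M <- pwm_log_odds(p_bg)
    w <- ncol(M)
    Mrc <- M[4:1, w:1, drop = FALSE]  # reverse-complement scoring matrix
    rownames(Mrc) <- DNA_BASES
    dist <- pwm_score_distribution(p_bg)
    # p-values come from per-column discretised scores, matching the DP atoms
    Mi <- round(M / dist$granularity)
    Mirc <- Mi[4:1, w:1, drop = FALSE]
    rownames(Mirc) <- DNA_BASES
    for (nm in names(codes_list)) {
      codes <- codes_list[[nm]]
      for (str in c("+", "-")) {
        sc <- window_scores(codes, if (str == "+") M else Mrc)
        sci <- window_scores(codes, if (str == "+") Mi else Mirc)
        if (!length(sc)) next
        pv <- rep(NA_real_, length(sc))
        ok <- !is.na(sc)
        pv[ok] <- score_pvalue_int(dist, sci[ok])
        hit <- which(ok & pv <= p_threshold)
        if (!length(hit)) next
        out[[length(out) + 1]] <- tibble(
          motif = p$name, chrom = nm,
          start = hit - 1, end = hit - 1 + w, strand = str,
          score = sc[hit], pvalue = pv[hit],
          matched = substr(rep(toupper(as.character(seqs[[nm]])), length(hit)),
                           hit, hit + w - 1)
        )
      }
    }
  }
  if (!length(out)) return(empty_hits())
  arrange(bind_rows(out), .data$motif, .data$chrom, .data$start, .data$strand)
}

empty_hits <- function() {
  tibble(motif = character(), chrom = character(), start = numeric(),
         end = numeric(), strand = character(), score = numeric(),
         pvalue = numeric(), matched = character())
}

#' Assign motif hits to peaks
#'
#' A hit belongs to a peak when it is fully contained in it.  Offsets are
#' measured from the hit centre to the peak reference point (the summit when
#' a `summit` column is present and non-missing, else the peak midpoint),
#' signed 5' to 3' on the forward genome strand.
#'
#' @param hits Hit tibble from [scan_motifs()].
#' @param peaks Interval tibble (optionally with a `summit` column).
#' @return A list with `peaks` (input plus `n_hits`, `has_motif`),
#'   `hits` (contained hits plus `peak_index`, `offset`), and
#'   `frac_with_motif`, the fraction of peaks containing at least one hit.
#' @export
motifs_in_peaks <- function(hits, peaks) {
  check_intervals(peaks, arg = "peaks")
  ref <- if ("summit" %in% names(peaks)) {
    ifelse(is.na(peaks$summit), (peaks$start + peaks$end) / 2, peaks$summit)
  } else {
    (peaks$start + peaks$end) / 2
  }
  n_hits <- integer(nrow(peaks))
  kept <- list()
  if (nrow(hits) && nrow(peaks)) {
    gh <- as_granges(hits[c("chrom", "start", "end")])
    gp <- as_granges(peaks[c("chrom", "start", "end")])
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gh, gp, type = "within"))
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    if (length(qi)) {
      tab <- table(si)
      n_hits[as.integer(names(tab))] <- as.integer(tab)
      kept <- hits[qi, ]
      kept$peak_index <- si
      kept$offset <- (kept$start + kept$end) / 2 - ref[si]
    }
  }
  peaks_out <- mutate(peaks, n_hits = n_hits, has_motif = n_hits > 0)
  list(peaks = peaks_out,
       hits = if (length(kept)) as_tibble(kept) else
         mutate(empty_hits(), peak_index = integer(), offset = numeric()),
       frac_with_motif = if (nrow(peaks)) mean(n_hits > 0) else NA_real_)
}
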
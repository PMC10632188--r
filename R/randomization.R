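# Sequence null models.
#
# All samplers use the session RNG: call set.seed() for reproducibility.
# "Horizontal" shuffles randomize one sequence internally (mononucleotide
# permutation, exact dinucleotide-preserving Eulerian shuffle, or a
# distance-matched mononucleotide shuffle); "vertical" sampling draws whole
# regions from position-specific base or conditional-dinucleotide
# probabilities fit across many aligned regions.

#' Mononucleotide shuffle
#'
#' Uniform random permutation of the letters; the base multiset is preserved
#' exactly.
#'
#' @param seq a single unambiguous DNA string.
#' @return shuffled string.
#' @export
shuffle_mono <- function(seq) {
  v <- .check_unambiguous(seq)
  ints_seq(v[sample.int(length(v))])
}

#' Dinucleotide-preserving shuffle (Altschul-Erickson)
#'
#' Exact dinucleotide shuffle by the Eulerian-path construction: the
#' sequence is viewed as an Eulerian walk on the 4-vertex base graph whose
#' edges are its dinucleotide steps. A random arborescence of "last exit"
#' edges toward the final base is drawn, remaining out-edges are randomly
#' ordered, and the walk is rebuilt. All 16 dinucleotide counts and the
#' first and last base are preserved exactly.
#'
#' @param seq a single unambiguous DNA string of length >= 2.
#' @return shuffled string with identical dinucleotide composition.
#' @export
shuffle_dinuc <- function(seq) {
  v <- .check_unambiguous(seq) + 1L   # 1..4
  L <- length(v)
  if (L < 2L) stop("sequence length must be >= 2 for dinucleotide shuffling")
  s1 <- v[1L]; sL <- v[L]
  adj <- vector("list", 4L)
  for (b in 1:4) adj[[b]] <- v[which(v[-L] == b) + 1L]
  sources <- which(lengths(adj) > 0L)
  if (length(sources) <= 1L && all(v == v[1L])) return(seq)

  pick_sources <- setdiff(sources, sL)
  # draw random last-exit edges until they form paths that all reach sL
  repeat {
    last_edge <- rep(NA_integer_, 4L)
    for (b in pick_sources) {
      outs <- adj[[b]]
      last_edge[b] <- outs[sample.int(length(outs), 1L)]
    }
    ok <- TRUE
    for (b in pick_sources) {
      cur <- b
      seen <- logical(4L)
      while (!is.na(cur) && cur != sL && !seen[cur]) {
        seen[cur] <- TRUE
        cur <- last_edge[cur]
      }
      if (is.na(cur) || cur != sL) { ok <- FALSE; break }
    }
    if (ok) break
  }

  queues <- vector("list", 4L)
  for (b in sources) {
    outs <- adj[[b]]
    if (b %in% pick_sources) {
      drop_idx <- match(last_edge[b], outs)
      rest <- outs[-drop_idx]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      queues[[b]] <- c(rest, last_edge[b])
    } else {
      queues[[b]] <- if (length(outs) > 1L) outs[sample.int(length(outs))] else outs
    }
  }

  out <- integer(L)
  out[1L] <- s1
  ptr <- rep(1L, 4L)
  cur <- s1
  for (i in 2:L) {
    nxt <- queues[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  ints_seq(out - 1L)
}

#' Count matching positions between two equal-length sequences
#'
#' @param a,b strings of equal length.
#' @return integer number of positions where the letters agree.
#' @export
count_matches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  sum(utf8ToInt(a) == utf8ToInt(b))
}

#' Distance-matched mononucleotide shuffle
#'
#' Shuffles a sequence at the single-base level by repeatedly exchanging two
#' randomly selected (unequal) bases until the result has exactly
#' `target_matches` positions in common with the original. Swaps that would
#' push the match count below the target are rejected, keeping the stopping
#' condition reachable. Used to build mononucleotide-shuffled sequences with
#' the same sequence distance from a parent as a paired
#' dinucleotide-preserving shuffle.
#'
#' @param seq a single unambiguous DNA string.
#' @param target_matches required number of matching positions,
#'   `0 <= target_matches <= nchar(seq)`.
#' @param max_iter swap-proposal budget (default `10000 * nchar(seq)`).
#' @return shuffled string with the same base multiset and exactly
#'   `target_matches` matches to `seq`. Unreachable targets (composition or
#'   parity constraints) or an exhausted budget raise an error of class
#'   `dnaflex_shuffle_error` naming the best achieved match count.
#' @export
matched_distance_shuffle <- function(seq, target_matches,
                                     max_iter = 10000L * nchar(seq)) {
  v <- .check_unambiguous(seq)
  L <- length(v)
  if (target_matches < 0L || target_matches > L) {
    stop("target_matches must be between 0 and the sequence length")
  }
  if (target_matches == L) return(seq)
  tab <- tabulate(v + 1L, 4L)
  if (max(tab) == L) {
    .shuffle_fail(L, target_matches)   # homopolymer: matches always L
  }
  cur <- v
  matches <- L
  best <- L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    i <- sample.int(L, 1L)
    j <- sample.int(L, 1L)
    if (cur[i] == cur[j]) next
    new_matches <- matches -
      (cur[i] == v[i]) - (cur[j] == v[j]) +
      (cur[j] == v[i]) + (cur[i] == v[j])
    if (new_matches < target_matches) next
    tmp <- cur[i]; cur[i] <- cur[j]; cur[j] <- tmp
    matches <- new_matches
    if (matches < best) best <- matches
    if (matches == target_matches) return(ints_seq(cur))
  }
  .shuffle_fail(best, target_matches)
}

.shuffle_fail <- function(best, target) {
  stop(structure(class = c("dnaflex_shuffle_error", "error", "condition"),
                 list(message = sprintf(
                   "could not reach target match count %d (best achieved: %d)",
                   target, best), call = sys.call(-1L))))
}

#' Fit a position-specific base model to aligned sequences
#'
#' Estimates, per offset, the marginal base probabilities and the
#' first-order conditional probabilities of each base given the preceding
#' one, from a set of equal-length aligned sequences (e.g. TSS-centered
#' regions). Ambiguous positions are excluded from the counts. This is the
#' model behind "vertical" sampling.
#'
#' @param aligned_seqs character vector of equal-length sequences.
#' @param pseudocount added to every count before normalization (default 0).
#' @return an object of class `positional_base_model`: list with L, p0
#'   (L x 4 matrix, rows sum to 1), trans ((L-1) x 4 x 4 array, rows sum
#'   to 1), pseudocount. Transition rows conditioned on a base never
#'   observed at an offset fall back to uniform (recorded in
#'   `uniform_fallback`).
#' @export
fit_positional_model <- function(aligned_seqs, pseudocount = 0) {
  if (length(aligned_seqs) < 1L) stop("need at least one sequence")
  m <- seqs_int_matrix(aligned_seqs)
  L <- nrow(m)
  if (L < 2L) stop("aligned sequences must have length >= 2")
  p0 <- matrix(0, L, 4L, dimnames = list(NULL, BASES))
  for (i in seq_len(L)) {
    cnt <- tabulate(m[i, ] + 1L, 4L) + pseudocount
    if (sum(cnt) == 0) {
      stop(sprintf("no usable observations at offset index %d with pseudocount 0", i))
    }
    p0[i, ] <- cnt / sum(cnt)
  }
  trans <- array(0, c(L - 1L, 4L, 4L),
                 dimnames = list(NULL, BASES, BASES))
  fallback <- matrix(FALSE, L - 1L, 4L)
  for (i in seq_len(L - 1L)) {
    a <- m[i, ]; b <- m[i + 1L, ]
    okp <- !is.na(a) & !is.na(b)
    cnt <- matrix(pseudocount, 4L, 4L)
    if (any(okp)) {
      tb <- table(factor(a[okp], levels = 0:3), factor(b[okp], levels = 0:3))
      cnt <- cnt + as.matrix(tb)
    }
    rs <- rowSums(cnt)
    zero <- rs == 0
    cnt[zero, ] <- 1
    rs[zero] <- 4
    fallback[i, ] <- zero
    trans[i, , ] <- cnt / rs
  }
  structure(list(L = L, p0 = p0, trans = trans, pseudocount = pseudocount,
                 uniform_fallback = fallback),
            class = "positional_base_model")
}

#' Sample sequences from a position-specific base model ("vertical")
#'
#' `order = "mono"` draws each base independently from the per-offset
#' marginal probabilities. `order = "dinuc"` grows the sequence base by
#' base: the first base from the offset-1 marginals, every later base from
#' the conditional probability of the four nucleotides given the previously
#' sampled base at the preceding offset (a position-inhomogeneous
#' first-order Markov chain).
#'
#' @param model a [fit_positional_model()] result.
#' @param order "mono" or "dinuc".
#' @param n number of sequences to draw.
#' @return character vector of `n` sequences of length `model$L`.
#' @export
sample_vertical <- function(model, order = c("dinuc", "mono"), n = 1L) {
  order <- match.arg(order)
  L <- model$L
  out <- matrix(0L, nrow = L, ncol = n)
  if (order == "mono") {
    for (i in seq_len(L)) {
      out[i, ] <- sample.int(4L, n, replace = TRUE, prob = model$p0[i, ]) - 1L
    }
  } else {
    out[1L, ] <- sample.int(4L, n, replace = TRUE, prob = model$p0[1L, ]) - 1L
    for (i in 2:L) {
      prev <- out[i - 1L, ]
      for (b in 0:3) {
        idx <- which(prev == b)
        if (length(idx) > 0L) {
          out[i, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                    prob = model$trans[i - 1L, b + 1L, ]) - 1L
        }
      }
    }
  }
  int_matrix_seqs(out)
}
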
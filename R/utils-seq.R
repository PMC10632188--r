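# Internal sequence encoding helpers shared by all modules.
# Bases are coded 0:3 in the fixed order A,C,G,T; dinucleotide index is
# 4*first + second + 1 (AA, AC, ..., TT).

BASES <- c("A", "C", "G", "T")
IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

DINUCS <- paste0(rep(BASES, each = 4), rep(BASES, times = 4))

# revcomp partner index of each dinucleotide (AA<->TT, AC<->GT, ...)
.dinuc_rc_index <- local({
  idx <- integer(16)
  for (i in 0:3) for (j in 0:3) {
    idx[4L * i + j + 1L] <- 4L * (3L - j) + (3L - i) + 1L
  }
  idx
})

.base_code <- local({
  code <- rep(NA_integer_, 256)
  code[utf8ToInt("A")] <- 0L
  code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L
  code[utf8ToInt("T")] <- 3L
  code
})

# Single sequence -> integer codes 0:3 (NA for any non-ACGT letter)
seq_ints <- function(seq) {
  .base_code[utf8ToInt(seq)]
}

ints_seq <- function(v) {
  intToUtf8(utf8ToInt("ACGT")[v + 1L])
}

# Equal-length sequences -> L x n integer matrix (NA = ambiguous)
seqs_int_matrix <- function(seqs) {
  L <- nchar(seqs[1L])
  if (length(seqs) > 1L && any(nchar(seqs) != L)) {
    stop("sequences must have equal length")
  }
  v <- utf8ToInt(paste(seqs, collapse = ""))
  matrix(.base_code[v], nrow = L)
}

int_matrix_seqs <- function(m) {
  chars <- c("A", "C", "G", "T")[m + 1L]
  dim(chars) <- dim(m)
  apply(chars, 2L, paste, collapse = "")
}

# n x 16 dinucleotide count matrix; rows with ambiguous letters are all-NA
dinuc_count_matrix <- function(seqs) {
  m <- seqs_int_matrix(seqs)
  L <- nrow(m)
  n <- ncol(m)
  if (L < 2L) stop("sequences must have length >= 2")
  idx <- 4L * m[-L, , drop = FALSE] + m[-1L, , drop = FALSE] + 1L
  counts <- matrix(0, nrow = n, ncol = 16L, dimnames = list(NULL, DINUCS))
  for (d in 1:16) {
    counts[, d] <- colSums(idx == d, na.rm = TRUE)
  }
  bad <- colSums(is.na(m)) > 0L
  counts[bad, ] <- NA_real_
  counts
}

.check_unambiguous <- function(seq, what = "sequence") {
  v <- seq_ints(seq)
  if (anyNA(v)) {
    off <- substr(seq, which(is.na(v))[1L], which(is.na(v))[1L])
    stop(sprintf("%s contains non-ACGT letter '%s'", what, off))
  }
  invisible(v)
}

#' Reverse complement of DNA sequences
#'
#' Strict reverse complement over the unambiguous alphabet A,C,G,T.
#' Vectorized over its input; ambiguity codes are an error because ambiguous
#' windows are dropped upstream of every scoring step.
#'
#' @param seq character vector of DNA sequences (A/C/G/T only).
#' @return character vector of the same length with each sequence reverse
#'   complemented. `revcomp(revcomp(x))` is the identity.
#' @examples
#' revcomp("AAC")   # "GTT"
#' revcomp("ACGT")  # palindromic
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    v <- .check_unambiguous(s)
    ints_seq(rev(3L - v))
  }, character(1L), USE.NAMES = FALSE)
}

#' One-hot encode a DNA sequence
#'
#' @param seq a single DNA string over A,C,G,T.
#' @return an `nchar(seq)` x 4 binary matrix with columns in the fixed order
#'   A,C,G,T; every row has exactly one 1.
#' @export
one_hot <- function(seq) {
  v <- .check_unambiguous(seq)
  m <- matrix(0L, nrow = length(v), ncol = 4L,
              dimnames = list(NULL, BASES))
  m[cbind(seq_along(v), v + 1L)] <- 1L
  m
}

# batch one-hot: n x L x 4 array for the neural predictor
one_hot_array <- function(seqs) {
  m <- seqs_int_matrix(seqs)            # L x n
  if (anyNA(m)) stop("ambiguous letters in sequences passed to one-hot encoding")
  L <- nrow(m)
  n <- ncol(m)
  X <- array(0, dim = c(n, L, 4L))
  tm <- t(m)                            # n x L
  for (b in 0:3) X[, , b + 1L][tm == b] <- 1
  X
}

# random unambiguous sequences (uses the session RNG)
random_seqs <- function(n, len, prob = rep(0.25, 4)) {
  m <- matrix(sample.int(4L, n * len, replace = TRUE, prob = prob) - 1L,
              nrow = len)
  int_matrix_seqs(m)
}
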
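# The predictor contract: a deterministic map from a 50-bp window to an
# intrinsic cyclizability score C0, always consumed through
# reverse-complement averaging. Two realizations live behind the contract:
# a linear dinucleotide model (exact, the testing surrogate and synthetic
# ground truth) and a trained neural regressor (see nn.R).

#' Score sequences with a predictor (raw, single orientation)
#'
#' Low-level scoring of the forward orientation only. Analyses should use
#' [predict_c0()], which averages forward and reverse-complement scores.
#'
#' @param p a predictor (`linear_dinuc_model`, `neural_net_predictor`, or a
#'   function wrapped by [as_flex_predictor()]).
#' @param seqs character vector of DNA sequences.
#' @return numeric vector of scores.
#' @export
score_raw <- function(p, seqs) UseMethod("score_raw")

#' Reverse-complement averaged cyclizability prediction
#'
#' Because loop-seq scores differ between a sequence and its reverse
#' complement, predictions are reported as the mean of the forward and
#' reverse-complement scores. The result is exactly invariant under reverse
#' complementation of the input.
#'
#' @inheritParams score_raw
#' @return numeric vector; `NA` for sequences containing ambiguous letters
#'   when `na_ambiguous = TRUE`, otherwise ambiguous input is an error.
#' @param na_ambiguous if TRUE, ambiguous sequences score NA instead of
#'   erroring (used by window pipelines that drop them).
#' @export
predict_c0 <- function(p, seqs, na_ambiguous = FALSE) {
  amb <- grepl("[^ACGT]", seqs)
  if (any(amb)) {
    if (!na_ambiguous) stop("ambiguous base in sequence passed to predict_c0")
    out <- rep(NA_real_, length(seqs))
    if (any(!amb)) out[!amb] <- predict_c0(p, seqs[!amb])
    return(out)
  }
  if (length(seqs) == 0L) return(numeric(0))
  (score_raw(p, seqs) + score_raw(p, revcomp(seqs))) / 2
}

#' Linear dinucleotide cyclizability model
#'
#' Additive surrogate model: `score(seq) = b + sum_i w[seq_i seq_{i+1}]`,
#' a weight per dinucleotide step plus an intercept. Serves as synthetic
#' ground truth and as an analytically tractable stand-in for the neural
#' regressor in oracle tests: its score depends only on the 16 dinucleotide
#' counts, so any dinucleotide-count-preserving shuffle leaves it unchanged.
#'
#' @param w numeric vector of 16 weights, named by dinucleotide (AA..TT) or
#'   given in that fixed order.
#' @param b intercept.
#' @return an object of classes `linear_dinuc_model`, `flex_predictor`.
#' @export
linear_dinuc_model <- function(w, b = 0) {
  if (length(w) != 16L) stop("w must have 16 dinucleotide weights")
  if (!is.null(names(w))) {
    if (!setequal(names(w), DINUCS)) stop("w names must be the 16 dinucleotides")
    w <- w[DINUCS]
  } else {
    names(w) <- DINUCS
  }
  if (any(!is.finite(c(w, b)))) stop("model parameters must be finite")
  structure(list(w = w, b = b, kind = "linear"),
            class = c("linear_dinuc_model", "flex_predictor"))
}

#' @export
print.linear_dinuc_model <- function(x, ...) {
  cat("<linear_dinuc_model> intercept", format(x$b), "\n")
  print(round(x$w, 4))
  invisible(x)
}

#' Evaluate a linear dinucleotide model on sequences
#'
#' @param model a [linear_dinuc_model()].
#' @param seq character vector of sequences (length >= 2 each, unambiguous).
#' @return numeric vector of scores.
#' @export
linear_dinuc_score <- function(model, seq) {
  if (any(nchar(seq) < 2L)) stop("sequence length must be >= 2")
  score_raw(model, seq)
}

#' @export
score_raw.linear_dinuc_model <- function(p, seqs) {
  counts <- dinuc_count_matrix(seqs)
  if (anyNA(counts)) stop("ambiguous base in sequence passed to linear model")
  drop(counts %*% p$w) + p$b
}

#' Wrap an arbitrary scoring function as a predictor
#'
#' Mainly for test stubs: `fn` must map a character vector of sequences to a
#' numeric vector of the same length, deterministically.
#'
#' @param fn scoring function.
#' @param kind free-text label stored as metadata.
#' @return an object of classes `function_predictor`, `flex_predictor`.
#' @export
as_flex_predictor <- function(fn, kind = "function") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, kind = kind),
            class = c("function_predictor", "flex_predictor"))
}

#' @export
score_raw.function_predictor <- function(p, seqs) {
  out <- p$fn(seqs)
  if (length(out) != length(seqs)) stop("predictor function returned wrong length")
  as.numeric(out)
}

#' Evaluate a predictor against a scored library
#'
#' Reverse-complement averaged predictions are compared with the library's
#' measured scores by Pearson correlation and by the median absolute
#' distance between predicted and actual score. Adapters are stripped from
#' raw 100-bp sequences first.
#'
#' @param p a predictor.
#' @param library data.frame with columns sequence, c0.
#' @return list with elements pearson_r (NA with `r_defined = FALSE` when
#'   predictions or targets are constant), median_abs_distance, n,
#'   r_defined.
#' @export
evaluate_predictor <- function(p, library) {
  if (nrow(library) == 0L) stop("empty library")
  probes <- strip_adapters(library$sequence)
  pred <- predict_c0(p, probes)
  mad_ <- stats::median(abs(pred - library$c0))
  if (stats::var(pred) == 0 || stats::var(library$c0) == 0) {
    return(list(pearson_r = NA_real_, median_abs_distance = mad_,
                n = nrow(library), r_defined = FALSE))
  }
  list(pearson_r = stats::cor(pred, library$c0),
       median_abs_distance = mad_, n = nrow(library), r_defined = TRUE)
}

#' Save a predictor as a JSON archive
#'
#' Stores weights, configuration and provenance in a single plain-text file
#' reloadable with [load_predictor()].
#'
#' @param p a `linear_dinuc_model` or `neural_net_predictor`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_predictor <- function(p, path) {
  obj <- if (inherits(p, "linear_dinuc_model")) {
    list(kind = "linear", w = as.list(p$w), b = p$b)
  } else if (inherits(p, "neural_net_predictor")) {
    list(kind = "neural", config = unclass(p$config),
         params = lapply(p$params, function(x) {
           list(dim = dim(x) %||% length(x), values = as.vector(x))
         }))
  } else {
    stop("cannot serialize this predictor type")
  }
  obj$package_version <- as.character(utils::packageVersion("dnaflex"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a predictor saved by [save_predictor()]
#' @param path path to the JSON archive.
#' @return the restored predictor.
#' @export
load_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "linear") {
    linear_dinuc_model(unlist(obj$w), obj$b)
  } else if (obj$kind == "neural") {
    params <- lapply(obj$params, function(x) {
      if (length(x$dim) > 1L) array(x$values, dim = x$dim) else x$values
    })
    cfg <- obj$config
    cfg$conv_blocks <- lapply(seq_len(nrow(cfg$conv_blocks)), function(i) {
      unlist(cfg$conv_blocks[i, , drop = TRUE])
    })
    new_neural_net_predictor(params, do.call(neural_net_config, cfg[
      setdiff(names(cfg), "conv_blocks_raw")]))
  } else {
    stop(sprintf("unknown predictor kind '%s'", obj$kind))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
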
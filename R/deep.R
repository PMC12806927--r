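#' Fine-tuning configuration for the deep sequence-pair classifier
#'
#' Records the hyperparameters used when fine-tuning a pretrained DNA
#' language model for loop prediction — learning rate 2e-4, 10% warmup,
#' 1% weight decay, 10% hidden dropout, pretrained model `"dnalongcat"`
#' (the long-sequence variant) — together with the settings of the
#' desk-scale stand-in classifier shipped here (`hidden_units`, `maxit`).
#' The configuration travels with any fitted deep handle so a downstream
#' fusion run can audit what produced the predictions.
#'
#' @param learning_rate Optimiser learning rate (> 0).
#' @param warmup_fraction Fraction of steps used for learning-rate warmup.
#' @param weight_decay L2 weight decay (also used as the stand-in's
#'   `nnet` decay).
#' @param hidden_dropout Hidden-layer dropout probability.
#' @param pretrained_model_name Name of the pretrained backbone.
#' @param hidden_units Hidden-layer width of the stand-in network.
#' @param maxit Optimiser iteration cap for the stand-in.
#' @return A list of class `dhl_finetune_config`.
#' @export
fine_tune_config <- function(learning_rate = 2e-4,
                             warmup_fraction = 0.10,
                             weight_decay = 0.01,
                             hidden_dropout = 0.10,
                             pretrained_model_name = "dnalongcat",
                             hidden_units = 16L,
                             maxit = 500L) {
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  for (nm in c("warmup_fraction", "weight_decay", "hidden_dropout")) {
    v <- get(nm)
    if (v < 0 || v >= 1) abort(paste0(nm, " must be in [0, 1)"))
  }
  structure(
    list(
      learning_rate = learning_rate, warmup_fraction = warmup_fraction,
      weight_decay = weight_decay, hidden_dropout = hidden_dropout,
      pretrained_model_name = pretrained_model_name,
      hidden_units = as.integer(hidden_units), maxit = as.integer(maxit)
    ),
    class = "dhl_finetune_config"
  )
}

#' Tokenize sequence pairs for the deep classifier
#'
#' Builds `[CLS] tokens(seq_a) [SEP] tokens(seq_b) [SEP]` per example,
#' maps tokens to 0-based vocabulary indices and right-pads with `[PAD]`
#' to `max_length`.  For window size `2 * flank` and token width `k` the
#' unpadded length is `2 * (2 * flank - k + 1) + 3` (511 at defaults).
#'
#' @param pairs Pair tibble (`seq_a`, `seq_b`).
#' @param vocab A [build_vocabulary()] object.
#' @param max_length Padded length; defaults to 515 (512 token positions
#'   plus the three specials), matching the 256 bp-per-anchor limit.
#' @return Integer matrix, one row per example (rownames = ids), entries
#'   0-based vocabulary indices.
#' @export
tokenize_pair <- function(pairs, vocab, max_length = 515L) {
  stopifnot(inherits(vocab, "dhl_vocabulary"))
  k <- vocab$k
  idx <- vocab$index
  ids <- pairs$id %||% paste0("ex", seq_len(nrow(pairs)))
  rows <- purrr::map2(pairs$seq_a, pairs$seq_b, function(a, b) {
    toks <- c("[CLS]", kmer_tokens(a, k), "[SEP]", kmer_tokens(b, k), "[SEP]")
    if (length(toks) > max_length) {
      abort(paste0(
        "tokenized pair length ", length(toks),
        " exceeds max_length ", max_length
      ))
    }
    ti <- idx[toks]
    if (anyNA(ti)) abort("token outside vocabulary") # unreachable by closure
    c(unname(ti), rep(idx[["[PAD]"]], max_length - length(toks)))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' Recover the two sequences from a tokenized pair
#'
#' Inverts [tokenize_pair()] for an unambiguous (ACGT-only) pair: strips
#' padding, splits the stream at the separator tokens and reconstructs
#' each sequence from its overlapping k-mers (first token plus the last
#' character of every following token).
#'
#' @param token_ids Integer vector of 0-based indices (one tokenized pair).
#' @param vocab The vocabulary used to tokenize.
#' @return A list with elements `seq_a` and `seq_b`.
#' @export
detokenize_pair <- function(token_ids, vocab) {
  stopifnot(inherits(vocab, "dhl_vocabulary"))
  toks <- vocab$tokens[token_ids + 1L]
  toks <- toks[toks != "[PAD]"]
  if (toks[1L] != "[CLS]" || toks[length(toks)] != "[SEP]") {
    abort("not a tokenized pair stream")
  }
  seps <- which(toks == "[SEP]")
  if (length(seps) != 2L) abort("expected exactly two [SEP] tokens")
  join <- function(tk) {
    if (any(tk == "[UNK]")) abort("cannot detokenize a stream containing [UNK]")
    paste0(tk[1L], paste(substring(tk[-1L], vocab$k, vocab$k), collapse = ""))
  }
  list(
    seq_a = join(toks[2:(seps[1L] - 1L)]),
    seq_b = join(toks[(seps[1L] + 1L):(seps[2L] - 1L)])
  )
}

#' Train the desk-scale deep stand-in classifier
#'
#' A small sequence-pair classifier honouring the same contract as a
#' fine-tuned transformer (fit on pair examples, predict aligned binary
#' labels and scores): the tokenized stream `[CLS] tokens(seq_a) [SEP]
#' tokens(seq_b) [SEP]` is embedded segment-wise — the average one-hot
#' token representation of each anchor's segment (its normalised
#' token-frequency vector over the vocabulary), concatenated so the pair
#' structure survives pooling — and classified by a single-hidden-layer
#' network (`nnet`, logistic output, L2 decay = `cfg$weight_decay`).
#' Token frequencies are standardised with training-set means and
#' standard deviations before the network (they are otherwise tiny
#' relative to the weight decay).  Trains in seconds on one CPU at
#' synthetic scale and is deterministic given `seed`.
#'
#' @param pairs Training pair tibble (`id`, `seq_a`, `seq_b`, `label`),
#'   both classes present.
#' @param cfg A [fine_tune_config()].
#' @param k Token width for the vocabulary.
#' @param seed Integer seed (weight initialisation).
#' @return A fitted handle of class `dhl_deep`; use
#'   [predict.dhl_deep()] on new pairs.
#' @export
train_standin <- function(pairs, cfg = fine_tune_config(), k = 3L, seed = 1L) {
  stopifnot(all(c("seq_a", "seq_b", "label") %in% names(pairs)))
  y <- as.integer(pairs$label)
  if (length(unique(y)) < 2L) {
    abort("training data must contain both classes")
  }
  vocab <- build_vocabulary(k)
  x <- token_frequency_matrix(pairs, vocab)
  center <- colMeans(x)
  scale_sd <- apply(x, 2L, stats::sd)
  scale_sd[scale_sd == 0] <- 1
  fit <- withr::with_seed(seed, {
    nnet::nnet(
      x = scale(x, center, scale_sd), y = y,
      size = cfg$hidden_units, decay = cfg$weight_decay,
      entropy = TRUE, maxit = cfg$maxit, trace = FALSE,
      MaxNWts = 100000L
    )
  })
  structure(
    list(
      fit = fit, vocab = vocab, cfg = cfg, seed = as.integer(seed),
      center = center, scale = scale_sd
    ),
    class = "dhl_deep"
  )
}

# Segment-wise average one-hot embedding of the tokenized stream: the
# token-frequency vector over the vocabulary of each anchor's segment
# (between [CLS]/[SEP] boundaries), concatenated.  Padding and the
# boundary specials carry no information and are excluded.
token_frequency_matrix <- function(pairs, vocab) {
  toks <- tokenize_pair(pairs, vocab,
    max_length = 2L * (max(nchar(c(pairs$seq_a, pairs$seq_b))) - vocab$k + 1L) + 3L
  )
  n_tok <- length(vocab$tokens)
  sep <- vocab$index[["[SEP]"]]
  rows <- apply(toks, 1L, function(ids) {
    seps <- which(ids == sep)
    seg_a <- ids[2:(seps[1L] - 1L)]
    seg_b <- ids[(seps[1L] + 1L):(seps[2L] - 1L)]
    c(
      tabulate(seg_a + 1L, nbins = n_tok) / length(seg_a),
      tabulate(seg_b + 1L, nbins = n_tok) / length(seg_b)
    )
  })
  m <- t(rows)
  colnames(m) <- c(paste0("a_", vocab$tokens), paste0("b_", vocab$tokens))
  m
}

#' @export
print.dhl_deep <- function(x, ...) {
  cat("<dhl_deep> stand-in sequence-pair classifier (k = ", x$vocab$k,
    ", hidden units = ", x$cfg$hidden_units, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Predict with the deep stand-in
#'
#' @param object A fitted [train_standin()] handle.
#' @param pairs Pair tibble to score.
#' @param ... Unused.
#' @return Prediction tibble: `id`, `label` (0/1, threshold 0.5), `score`.
#' @export
predict.dhl_deep <- function(object, pairs, ...) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(id = character(), label = integer(), score = numeric()))
  }
  x <- scale(token_frequency_matrix(pairs, object$vocab), object$center, object$scale)
  score <- as.numeric(predict(object$fit, x))
  tibble::tibble(
    id = pairs$id %||% paste0("ex", seq_len(nrow(pairs))),
    label = as.integer(score >= 0.5),
    score = score
  )
}

#' Write predictions as tab-separated `id label score`
#'
#' @param predictions Prediction tibble (`id`, `label`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("id", "label", "score") %in% names(predictions)))
  lines <- c(
    "id\tlabel\tscore",
    sprintf(
      "%s\t%d\t%.17g", predictions$id,
      as.integer(predictions$label), predictions$score
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Import externally produced predictions
#'
#' Reads tab-separated `id label score` files (e.g. outputs of a genuine
#' fine-tuned transformer run elsewhere) so they can be fused in place of
#' the stand-in.  Scores must lie in `[0, 1]`; when `expected_ids` is
#' given the file must cover them all and the result is returned in that
#' order.
#'
#' @param path Path to the predictions file.
#' @param expected_ids Optional identifiers the file must cover.
#' @return Prediction tibble: `id`, `label`, `score`.
#' @export
import_external_predictions <- function(path, expected_ids = NULL) {
  if (!file.exists(path)) {
    abort(paste0("predictions file not found: ", path))
  }
  lines <- readLines(path)
  if (length(lines) > 0L && lines[1L] == "id\tlabel\tscore") {
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    preds <- tibble::tibble(id = character(), label = integer(), score = numeric())
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 3L)
    if (length(bad) > 0L) {
      abort(paste0("malformed prediction row at line ", bad[1L]))
    }
    m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
    label <- suppressWarnings(as.integer(m[, 2L]))
    score <- suppressWarnings(as.numeric(m[, 3L]))
    if (anyNA(label) || !all(label %in% c(0L, 1L))) {
      abort("prediction labels must be 0 or 1")
    }
    if (anyNA(score) || any(score < 0 | score > 1)) {
      abort("prediction scores must lie in [0, 1]")
    }
    preds <- tibble::tibble(id = m[, 1L], label = label, score = score)
  }
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, preds$id)
    if (length(missing) > 0L) {
      abort(paste0(
        "predictions missing for id(s): ",
        paste(head(missing, 10L), collapse = ", "),
        if (length(missing) > 10L) paste0(" (+", length(missing) - 10L, " more)") else ""
      ))
    }
    preds <- preds[match(expected_ids, preds$id), , drop = FALSE]
  }
  preds
}
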
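#' Accessibility predictor contract
#'
#' A predictor is a list of class `accessibility_predictor` declaring
#' `input_length` (its receptive field, bp), `tracks` (character vector of
#' track ids) and `predict`, a function mapping a character vector of
#' sequences (each exactly `input_length` bp) to an `n x length(tracks)`
#' matrix of P(accessible) values in [0, 1]. Predictions must be
#' deterministic for a fixed predictor. The pipeline is agnostic to the
#' predictor's internals; any model honouring this contract (including
#' large pre-trained multi-track models) can be plugged in. The reference
#' implementation shipped here is a small one-layer convolutional network
#' trained on synthetic motif data ([train_reference_predictor()]).
#'
#' @name accessibility_predictor
NULL

new_predictor <- function(input_length, tracks, predict_fun, meta = list()) {
  structure(list(input_length = as.integer(input_length),
                 tracks = tracks, predict = predict_fun, meta = meta),
            class = "accessibility_predictor")
}

#' Constant-output predictor (stub for tests and degenerate baselines)
#'
#' @param values Named numeric vector of per-track constant outputs in
#'   [0, 1]; names are track ids.
#' @param input_length Declared input length.
#' @return An [accessibility_predictor].
#' @export
constant_predictor <- function(values, input_length = 200L) {
  stopifnot(all(values >= 0 & values <= 1), !is.null(names(values)))
  force(values)
  new_predictor(input_length, names(values), function(seqs) {
    matrix(rep(values, each = length(seqs)), nrow = length(seqs),
           dimnames = list(NULL, names(values)))
  })
}

#' Predict accessibility for sequences
#'
#' Validates lengths against the predictor's declared receptive field and
#' returns per-track P(accessible) values.
#'
#' @param seqs Character vector of DNA sequences.
#' @param model An [accessibility_predictor].
#' @return Numeric matrix, `length(seqs)` rows, one column per track,
#'   values in [0, 1].
#' @export
predict_accessibility <- function(seqs, model) {
  stopifnot(inherits(model, "accessibility_predictor"))
  bad <- which(nchar(seqs) != model$input_length)
  if (length(bad)) {
    stop("sequence ", bad[1], " has length ", nchar(seqs[bad[1]]),
         "; model expects ", model$input_length, call. = FALSE)
  }
  p <- model$predict(toupper(seqs))
  p <- matrix(pmin(pmax(p, 0), 1), nrow = length(seqs),
              dimnames = list(NULL, model$tracks))
  p
}

# A=1 C=2 G=3 T=4, anything else 0 (contributes nothing to the convolution)
encode_dna <- function(seq) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  code[utf8ToInt(seq)]
}

# Convolution activations for one encoded sequence: positions x filters.
# W is a (4*w) x K matrix viewed as (base, offset) x filter.
conv_forward <- function(code, W, b, w) {
  P <- length(code) - w + 1L
  K <- ncol(W)
  A <- matrix(rep(b, each = P), P, K)
  for (j in seq_len(w)) {
    cj <- code[j:(j + P - 1L)]
    nz <- cj > 0L
    if (any(nz)) {
      A[nz, ] <- A[nz, ] + W[(j - 1L) * 4L + cj[nz], , drop = FALSE]
    }
  }
  A
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# leaky rectifier: keeps a small gradient on the negative side so filters
# cannot die irrecoverably during the per-sample updates
lrelu <- function(x, alpha = 0.1) pmax(x, 0) + alpha * pmin(x, 0)
lrelu_grad <- function(x, alpha = 0.1) ifelse(x > 0, 1, alpha)

#' Train the reference convolutional accessibility predictor
#'
#' A one-convolutional-layer network: K motif filters of fixed width,
#' leaky-ReLU, global max-pooling over positions, and a logistic output
#' head;
#' trained with per-sample Adam updates on binary cross-entropy. Training
#' is fully reproducible for a fixed seed. Intended as the synthetic-data
#' reference implementation of the [accessibility_predictor] contract; it
#' exposes a single track, `"synthetic_accessibility"`.
#'
#' @param dataset List with `sequences` (equal-length character vector)
#'   and `labels` (0/1); both classes must be present.
#' @param seed RNG seed for weight initialisation and shuffling.
#' @param n_filters Number of convolution filters.
#' @param filter_width Filter width in bp.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @return A trained [accessibility_predictor].
#' @export
train_reference_predictor <- function(dataset, seed = 7L, n_filters = 8L,
                                      filter_width = 10L, epochs = 12L,
                                      lr = 0.02) {
  seqs <- toupper(dataset$sequences)
  y <- as.numeric(dataset$labels)
  if (length(unique(y)) < 2L) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  codes <- lapply(seqs, encode_dna)
  w <- as.integer(filter_width); K <- as.integer(n_filters)
  with_seed(seed, {
    W1 <- matrix(stats::rnorm(4L * w * K, sd = 0.1), 4L * w, K)
    b1 <- rep(0, K)
    W2 <- stats::rnorm(K, sd = 0.1)
    b2 <- 0
    # Adam state
    mW1 <- vW1 <- matrix(0, 4L * w, K); mb1 <- vb1 <- rep(0, K)
    mW2 <- vW2 <- rep(0, K); mb2 <- vb2 <- 0
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
    n <- length(codes)
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        code <- codes[[i]]
        A <- conv_forward(code, W1, b1, w)
        H <- lrelu(A)
        amax <- max.col(t(H), ties.method = "first")  # argmax position per filter
        h <- H[cbind(amax, seq_len(K))]
        z <- sum(h * W2) + b2
        p <- sigmoid(z)
        dz <- p - y[i]
        gW2 <- dz * h; gb2 <- dz
        dh <- dz * W2
        dh <- dh * lrelu_grad(A[cbind(amax, seq_len(K))])
        gW1 <- matrix(0, 4L * w, K); gb1 <- dh
        for (k in seq_len(K)) {
          if (dh[k] == 0) next
          pstar <- amax[k]
          for (j in seq_len(w)) {
            cj <- code[pstar + j - 1L]
            if (cj > 0L) {
              r <- (j - 1L) * 4L + cj
              gW1[r, k] <- gW1[r, k] + dh[k]
            }
          }
        }
        t <- t + 1
        adam <- function(g, m, v) {
          m <- beta1 * m + (1 - beta1) * g
          v <- beta2 * v + (1 - beta2) * g^2
          mhat <- m / (1 - beta1^t); vhat <- v / (1 - beta2^t)
          list(step = lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
        }
        u <- adam(gW1, mW1, vW1); W1 <- W1 - u$step; mW1 <- u$m; vW1 <- u$v
        u <- adam(gb1, mb1, vb1); b1 <- b1 - u$step; mb1 <- u$m; vb1 <- u$v
        u <- adam(gW2, mW2, vW2); W2 <- W2 - u$step; mW2 <- u$m; vW2 <- u$v
        u <- adam(gb2, mb2, vb2); b2 <- b2 - u$step; mb2 <- u$m; vb2 <- u$v
      }
    }
    weights <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, w = w, K = K)
  })
  predict_fun <- function(seqs) {
    out <- vapply(seqs, function(s) {
      A <- conv_forward(encode_dna(s), weights$W1, weights$b1, weights$w)
      h <- apply(lrelu(A), 2, max)
      sigmoid(sum(h * weights$W2) + weights$b2)
    }, numeric(1), USE.NAMES = FALSE)
    matrix(out, ncol = 1, dimnames = list(NULL, "synthetic_accessibility"))
  }
  new_predictor(L, "synthetic_accessibility", predict_fun,
                meta = list(weights = weights, seed = seed,
                            epochs = epochs, lr = lr))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation; ties get midranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Apply an in-silico base edit to a reference context
#'
#' Converts the named protospacer-window adenines to G on the protospacer
#' strand. For a plus-strand protospacer this is A->G at the mapped
#' reference offsets; for a minus-strand protospacer the reference
#' plus-strand context shows T->C at the mirrored offsets. Length is
#' preserved.
#'
#' @param ref_context Reference plus-strand sequence containing the
#'   protospacer.
#' @param spec [protospacer_spec()] (window bounds are validated against
#'   it).
#' @param positions Protospacer positions to edit (each must carry A on
#'   the protospacer strand); the empty set returns the input unchanged.
#' @param proto_start 0-based start of the protospacer span within
#'   `ref_context`.
#' @param strand Protospacer strand relative to `ref_context`.
#' @return The edited context string.
#' @export
apply_edit <- function(ref_context, spec, positions, proto_start,
                       strand = "+") {
  positions <- as.integer(positions)
  if (!length(positions)) return(ref_context)
  stopifnot(all(positions >= spec$editing_window[1] &
                positions <= spec$editing_window[2]))
  chars <- strsplit(ref_context, "")[[1]]
  for (p in positions) {
    idx <- if (strand == "+") proto_start + p else proto_start + 21L - p
    if (idx < 1L || idx > length(chars)) {
      stop("position ", p, " maps outside the context", call. = FALSE)
    }
    want <- if (strand == "+") "A" else "T"
    if (chars[idx] != want) {
      stop("protospacer position ", p, " does not carry an adenine on the ",
           "protospacer strand (reference base '", chars[idx], "')",
           call. = FALSE)
    }
    chars[idx] <- if (strand == "+") "G" else "C"
  }
  paste(chars, collapse = "")
}

window_adenines <- function(protospacer, spec) {
  win <- spec$editing_window[1]:spec$editing_window[2]
  win[substring(protospacer, win, win) == "A"]
}

#' Damage-score one candidate site
#'
#' Extracts the model-length reference context centred on the protospacer,
#' evaluates each single window-adenine edit plus the all-adenines edit
#' (the default edit set; configurable), and computes the damage score
#' `P(accessible)_control - P(accessible)_edited` per track and edit. The
#' model always sees the protospacer-strand orientation, so a site gives
#' identical results under either strand representation. A site is flagged
#' when some track has `P(accessible)_control > p_threshold` and damage
#' `> damage_threshold` (defaults 0.2 and 0.1). Gain-of-function edits
#' (negative damage, edited more accessible) keep their sign and are only
#' flagged when `flag_absolute = TRUE`.
#'
#' @param site One row of a [candidate_sites] data.frame (must have an
#'   adenine in the editing window).
#' @param genome Named character vector of contig sequences.
#' @param spec [protospacer_spec()].
#' @param model An [accessibility_predictor].
#' @param p_threshold Control-accessibility threshold (default 0.2).
#' @param damage_threshold Damage threshold (default 0.1).
#' @param edit_sets `"singles+all"` (default) or a list of integer vectors
#'   of protospacer positions to evaluate.
#' @param flag_absolute Flag on `|damage|` instead of signed damage.
#' @return List of class `damage_result`: `site_id`, `p_control` (named by
#'   track), `edits` (data.frame: edit description, per-track p_edited and
#'   damage), `max_damage`, `flagged`.
#' @export
score_site <- function(site, genome, spec, model, p_threshold = 0.2,
                       damage_threshold = 0.1, edit_sets = "singles+all",
                       flag_absolute = FALSE) {
  proto <- site$protospacer
  adenines <- window_adenines(proto, spec)
  if (!length(adenines)) {
    stop("site ", site_ids(site), " has no adenine in the editing window ",
         "(should have been filtered)", call. = FALSE)
  }
  len <- model$input_length
  cseq <- genome[[site$contig]]
  mid <- (site$start + site$end) %/% 2L
  ctx_start0 <- mid - len %/% 2L
  if (ctx_start0 < 0L || ctx_start0 + len > nchar(cseq)) {
    stop("context of length ", len, " around ", site_ids(site),
         " exceeds contig bounds", call. = FALSE)
  }
  context <- substr(cseq, ctx_start0 + 1L, ctx_start0 + len)
  proto_start <- site$start - ctx_start0  # 0-based within context
  if (identical(edit_sets, "singles+all")) {
    edit_sets <- lapply(adenines, identity)
    if (length(adenines) > 1L) edit_sets <- c(edit_sets, list(adenines))
  }
  orient <- function(x) if (site$strand == "+") x else reverse_complement(x)
  p_control <- predict_accessibility(orient(context), model)[1, ]
  edits <- lapply(edit_sets, function(pos) {
    edited <- apply_edit(context, spec, pos, proto_start, site$strand)
    p_edited <- predict_accessibility(orient(edited), model)[1, ]
    list(positions = pos, p_edited = p_edited,
         damage = p_control - p_edited)
  })
  dmg <- do.call(rbind, lapply(edits, function(e) e$damage))
  rownames(dmg) <- vapply(edits, function(e) {
    paste0("A", paste(e$positions, collapse = "+A"), ">G")
  }, character(1))
  eff_dmg <- if (flag_absolute) abs(dmg) else dmg
  flag_mat <- sweep(eff_dmg > damage_threshold, 2,
                    p_control > p_threshold, "&")
  structure(list(
    site_id = site_ids(site),
    p_control = p_control,
    edits = data.frame(edit = rownames(dmg),
                       p_edited = do.call(rbind,
                                          lapply(edits, `[[`, "p_edited")),
                       damage = dmg, row.names = NULL),
    max_damage = max(dmg),
    flagged = any(flag_mat)
  ), class = "damage_result")
}

#' Damage-score many candidate sites
#'
#' @inheritParams score_site
#' @param sites A [candidate_sites] data.frame (all rows must have a
#'   window adenine; use [filter_adenine_window()] first).
#' @return data.frame with one row per site: `site`, `p_control` (maximum
#'   over tracks), `max_damage`, `flagged`; full per-edit results as the
#'   `"results"` attribute.
#' @export
score_sites <- function(sites, genome, spec, model, p_threshold = 0.2,
                        damage_threshold = 0.1, edit_sets = "singles+all",
                        flag_absolute = FALSE) {
  res <- lapply(seq_len(nrow(sites)), function(i) {
    score_site(sites[i, , drop = FALSE], genome, spec, model,
               p_threshold = p_threshold,
               damage_threshold = damage_threshold,
               edit_sets = edit_sets, flag_absolute = flag_absolute)
  })
  df <- data.frame(
    site = vapply(res, `[[`, character(1), "site_id"),
    p_control = vapply(res, function(r) max(r$p_control), numeric(1)),
    max_damage = vapply(res, `[[`, numeric(1), "max_damage"),
    flagged = vapply(res, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE)
  attr(df, "results") <- res
  df
}
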
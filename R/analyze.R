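#' Fisher-style class separability (J-score)
#'
#' Between-class scatter is the outer product of the class-mean difference;
#' within-class scatter sums the centered outer products of both classes. The
#' scalar score is trace(Sb) / trace(Sw), i.e. the squared distance between
#' the class means divided by the total within-class squared deviation. Higher
#' means better separated classes; the score is invariant to translation and
#' orthogonal transformation of the features.
#'
#' @param features numeric matrix (samples x dimensions) or vector (1-D).
#' @param labels parallel "positive"/"negative" vector.
#' @return a `j_score_result`: list with `j`, `s_b_trace`, `s_w_trace`,
#'   `dimension` and the `infinite_separation` flag (TRUE when the
#'   within-class scatter is exactly zero).
#' @export
j_score <- function(features, labels) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  y <- as.character(labels)
  if (nrow(features) != length(y)) stop_invalid("features/labels length mismatch")
  if (!all(c("positive", "negative") %in% y)) {
    stop_invalid("both classes required for the J-score")
  }
  pos <- features[y == "positive", , drop = FALSE]
  neg <- features[y == "negative", , drop = FALSE]
  mp <- colMeans(pos); mn <- colMeans(neg)
  s_b <- sum((mp - mn)^2)
  s_w <- sum(sweep(pos, 2, mp)^2) + sum(sweep(neg, 2, mn)^2)
  structure(list(
    j = if (s_w > 0) s_b / s_w else Inf,
    s_b_trace = s_b, s_w_trace = s_w,
    dimension = ncol(features),
    infinite_separation = s_w == 0
  ), class = "j_score_result")
}

#' @export
print.j_score_result <- function(x, ...) {
  cat(sprintf("J-score: %g (trace Sb %g / trace Sw %g, dim %d)\n",
              x$j, x$s_b_trace, x$s_w_trace, x$dimension))
  invisible(x)
}

# deterministic-sign PCA: each component's largest-magnitude loading is positive
pca_project <- function(x, target_dim) {
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- p$rotation[, seq_len(target_dim), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scale(x, center = TRUE, scale = FALSE) %*% rot
}

# exact (O(n^2)) t-SNE; adequate for the visualization sample sizes used here
tsne_exact <- function(x, target_dim = 2, perplexity = 30, max_iter = 500, seed = 1) {
  n <- nrow(x)
  if (n < 4) stop_invalid("t-SNE needs at least 4 samples")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  d2 <- as.matrix(stats::dist(x))^2
  if (max(d2) == 0) stop_invalid("t-SNE: degenerate input (all points identical)")
  # per-point precision by binary search on perplexity
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(di), length(di)) else p <- p / sp
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - logU) < 1e-5) break
      if (h > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * target_dim, sd = 1e-4), n, target_dim)
  gains <- matrix(1, n, target_dim)
  inc <- matrix(0, n, target_dim)
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= 100) P * 4 else P  # early exaggeration
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - 200 * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }
  Y
}

#' Reduce features to 2 or 3 dimensions for visualization
#'
#' PCA is deterministic with a fixed sign convention (the largest-magnitude
#' loading of each component is positive); t-SNE is seeded and therefore
#' reproducible for a fixed seed. Rows of the output align with rows of the
#' input.
#'
#' @param features numeric matrix.
#' @param target_dim 2 or 3.
#' @param method "pca" or "tsne".
#' @param seed integer seed (t-SNE only).
#' @param perplexity t-SNE perplexity (default 30; reduced automatically for
#'   small n).
#' @return n x target_dim coordinate matrix.
#' @export
reduce_features <- function(features, target_dim = 2, method = c("pca", "tsne"),
                            seed = 1, perplexity = 30) {
  method <- match.arg(method)
  if (!target_dim %in% c(2, 3)) stop_invalid("target_dim must be 2 or 3")
  if (target_dim >= ncol(features)) stop_invalid("target_dim must be below input dimension")
  if (nrow(features) < target_dim + 1) stop_invalid("too few samples")
  if (method == "pca") {
    if (max(abs(sweep(features, 2, colMeans(features)))) == 0) {
      warning("zero-variance input; PCA coordinates are all zero")
    }
    out <- pca_project(features, target_dim)
  } else {
    out <- tsne_exact(features, target_dim, perplexity = perplexity, seed = seed)
  }
  rownames(out) <- rownames(features)
  colnames(out) <- paste0("dim", seq_len(target_dim))
  out
}

#' Complement / reverse-complement symmetry of an embedding table
#'
#' Projects all k-mer vectors with 2-D PCA, pairs each token with its
#' complement and with its reverse complement, and reports the second
#' principal coordinate of both members of each pair. A mirror arrangement
#' about the first principal axis shows up as `y2 ~ -y1`; the summary score is
#' the Pearson correlation between y of a token and -y of its partner
#' (self-paired tokens, e.g. reverse-complement palindromes, are listed with
#' their |y| but excluded from the correlation).
#'
#' @param table an `embedding_table`.
#' @param projection_dim number of principal components used (>= 2).
#' @return list with `pairs` (data.frame token/partner/relation/y1/y2/self)
#'   and `symmetry_score` (per relation and overall).
#' @export
symmetry_report <- function(table, projection_dim = 2) {
  stopifnot(inherits(table, "embedding_table"), projection_dim >= 2)
  toks <- rownames(table$vectors)
  if (length(toks) == 0) stop_invalid("empty vocabulary")
  proj <- pca_project(table$vectors, projection_dim)
  y <- proj[, 2]
  names(y) <- toks
  comp <- chartr("ACGT", "TGCA", toks)
  rc <- revcomp_chr(toks)
  mk <- function(partner, relation) {
    present <- partner %in% toks
    data.frame(token = toks[present], partner = partner[present],
               relation = relation,
               y1 = unname(y[toks[present]]), y2 = unname(y[partner[present]]),
               self = toks[present] == partner[present],
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk(comp, "complement"), mk(rc, "reverse_complement"))
  score_of <- function(df) {
    df <- df[!df$self, ]
    if (nrow(df) < 3 || stats::sd(df$y1) == 0 || stats::sd(df$y2) == 0) return(NA_real_)
    stats::cor(df$y1, -df$y2)
  }
  list(
    pairs = pairs,
    symmetry_score = c(
      complement = score_of(pairs[pairs$relation == "complement", ]),
      reverse_complement = score_of(pairs[pairs$relation == "reverse_complement", ]),
      overall = score_of(pairs)
    )
  )
}
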
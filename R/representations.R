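#' Diagonal-Gaussian latent representation
#'
#' The posterior produced by a beta-VAE encoder for one stimulus: a mean and
#' log-variance vector over the latent units.
#'
#' @param mean Numeric vector of posterior means.
#' @param logvar Numeric vector of posterior log-variances, same length.
#' @return A `gaussian_representation`.
#' @export
gaussian_representation <- function(mean, logvar = rep(0, length(mean))) {
  if (length(mean) != length(logvar)) stop("mean and logvar lengths differ")
  if (any(!is.finite(mean)) || any(!is.finite(logvar)))
    stop("representation entries must be finite")
  structure(list(mean = as.numeric(mean), logvar = as.numeric(logvar),
                 dim = length(mean)), class = "gaussian_representation")
}

#' KL divergence between diagonal Gaussians
#'
#' Closed-form `KL(p || q)` for diagonal-Gaussian posteriors; nonnegative, and
#' zero iff the distributions coincide.
#'
#' @param p,q `gaussian_representation` objects of equal dimension.
#' @return Nonnegative scalar.
#' @examples
#' p <- gaussian_representation(0, 0); q <- gaussian_representation(1, 0)
#' kl_divergence(p, q) # 0.5
#' @export
kl_divergence <- function(p, q) {
  if (p$dim != q$dim) stop("dimension mismatch")
  vp <- exp(p$logvar); vq <- exp(q$logvar)
  0.5 * sum(q$logvar - p$logvar + (vp + (p$mean - q$mean)^2) / vq - 1)
}

#' KL-based similarity between Gaussian representations
#'
#' KL divergence is asymmetric and unbounded; as a similarity for the IBL
#' partial-matching term it is symmetrized and passed through a negative
#' exponential: `exp(-KL_sym / lambda)` with
#' `KL_sym = (KL(p||q) + KL(q||p)) / 2`. Self-similarity is exactly 1 and
#' values lie in (0, 1].
#'
#' @param p,q `gaussian_representation` objects of equal dimension.
#' @param lambda Positive scale of the exponential mapping.
#' @param raw If `TRUE`, return `-KL_sym` instead of the bounded similarity.
#' @return Similarity in (0, 1] (or a nonpositive value when `raw = TRUE`).
#' @export
kl_similarity <- function(p, q, lambda = 1, raw = FALSE) {
  if (lambda <= 0) stop("lambda must be > 0")
  kl_sym <- 0.5 * (kl_divergence(p, q) + kl_divergence(q, p))
  if (raw) return(-kl_sym)
  exp(-kl_sym / lambda)
}

#' Cosine similarity between embeddings
#'
#' `dot(u, v) / (|u| |v|)`, clamped to `[-1, 1]` against rounding error.
#'
#' @param u,v Numeric vectors of equal length, neither all-zero.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Similarity function over representation attributes
#'
#' Wraps a generative-model similarity metric so it can be installed in a
#' [similarity_spec()] under the reserved `"repr"` attribute. `"kl"` compares
#' `gaussian_representation` objects via [kl_similarity()]; `"cosine"`
#' compares embedding vectors (optionally rescaled to `[0, 1]` via
#' `(1 + cos) / 2`).
#'
#' @param metric `"kl"` or `"cosine"`.
#' @param lambda Scale of the KL similarity mapping.
#' @param rescale Rescale cosine to `[0, 1]`? Default `FALSE` (raw cosine).
#' @return A similarity function for [similarity_spec()].
#' @export
sim_gm <- function(metric = c("kl", "cosine"), lambda = 1, rescale = FALSE) {
  metric <- match.arg(metric)
  if (metric == "kl") {
    function(a, b) kl_similarity(a, b, lambda = lambda)
  } else {
    function(a, b) {
      s <- cosine_similarity(a, b)
      if (rescale) (1 + s) / 2 else s
    }
  }
}

# ---------------------------------------------------------------------------
# Synthetic visual stimuli

stimulus_shapes   <- c("circle", "square", "triangle")
stimulus_colors   <- c("yellow", "red", "green")
stimulus_textures <- c("dotted", "wavy", "hatched")

color_rgb <- function(color) {
  switch(color,
         yellow = c(1, 1, 0), red = c(1, 0, 0), green = c(0, 1, 0),
         gray = c(0.6, 0.6, 0.6),
         stop("unknown color '", color, "'"))
}

#' Render a synthetic stimulus image
#'
#' Deterministically renders a shape/color/texture combination as an
#' `size x size x 3` array in `[0, 1]`. Color and texture may be `NULL`
#' (early transfer phases show shape-only stimuli), in which case a neutral
#' gray fill and solid texture are used. Distinct specs produce distinct
#' images.
#'
#' @param shape One of `"circle"`, `"square"`, `"triangle"`.
#' @param color One of `"yellow"`, `"red"`, `"green"`, or `NULL`.
#' @param texture One of `"dotted"`, `"wavy"`, `"hatched"`, or `NULL`.
#' @param size Image side length in pixels.
#' @return Numeric array `size x size x 3`.
#' @export
render_stimulus <- function(shape, color = NULL, texture = NULL, size = 32L) {
  if (!shape %in% stimulus_shapes) stop("unknown shape '", shape, "'")
  if (!is.null(color) && !color %in% stimulus_colors)
    stop("unknown color '", color, "'")
  if (!is.null(texture) && !texture %in% stimulus_textures)
    stop("unknown texture '", texture, "'")
  xy <- (seq_len(size) - 0.5) / size - 0.5        # centered coords in [-0.5,0.5]
  X <- matrix(xy, size, size, byrow = TRUE)       # column coordinate
  Y <- matrix(xy, size, size)                     # row coordinate
  mask <- switch(shape,
    circle = (X^2 + Y^2) <= 0.4^2,
    square = pmax(abs(X), abs(Y)) <= 0.35,
    triangle = (Y >= -0.35) & (abs(X) <= 0.45 * (0.38 - Y) / 0.76) & (Y <= 0.41))
  rows <- row(X); cols <- col(X)
  tex <- switch(if (is.null(texture)) "solid" else texture,
    solid = matrix(1, size, size),
    dotted = 0.45 + 0.55 * (((rows %% 6) < 3) & ((cols %% 6) < 3)),
    wavy = 0.45 + 0.55 * (sin(2 * pi * 4 * (Y + 0.5) +
                              3 * sin(2 * pi * 2 * (X + 0.5))) > 0),
    hatched = 0.45 + 0.55 * (((rows + cols) %% 6) < 3))
  rgb <- color_rgb(if (is.null(color)) "gray" else color)
  img <- array(0, c(size, size, 3L))
  for (ch in 1:3) img[, , ch] <- mask * tex * rgb[ch]
  img
}

#' Enumerate stimulus specifications
#'
#' The full factorial crossing of the active stimulus dimensions. With all
#' three dimensions active this is the 27-stimulus set of the contextual
#' bandit task.
#'
#' @param dims Character vector among `"shape"`, `"color"`, `"texture"`.
#' @return A data.frame with one row per stimulus.
#' @export
stimulus_grid <- function(dims = c("shape", "color", "texture")) {
  levels <- list(shape = stimulus_shapes, color = stimulus_colors,
                 texture = stimulus_textures)
  unknown <- setdiff(dims, names(levels))
  if (length(unknown)) stop("unknown stimulus dimension: ", unknown[1])
  expand.grid(levels[dims], KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# beta-VAE: dense encoder/decoder trained by reparameterized gradients.

#' beta-VAE specification
#'
#' @param latent_dim Number of latent units (default 9).
#' @param beta Weight of the KL term (information bottleneck), `beta >= 0`.
#' @param hidden Width of the single hidden layer in encoder and decoder.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param seed Integer seed.
#' @return A `bvae_spec`.
#' @export
bvae_spec <- function(latent_dim = 9L, beta = 1, hidden = 64L,
                      epochs = 200L, lr = 1e-2, seed = 1L) {
  if (latent_dim < 1) stop("latent_dim must be >= 1")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(latent_dim = as.integer(latent_dim), beta = beta,
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed)), class = "bvae_spec")
}

images_to_matrix <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L)
    images <- list(images)
  do.call(rbind, lapply(images, function(im) as.numeric(im)))
}

#' Train a beta-VAE on a set of images
#'
#' A variational autoencoder with dense encoder and decoder and a diagonal-
#' Gaussian latent posterior. The loss is per-image summed squared
#' reconstruction error plus `beta` times the KL divergence of the posterior
#' from the standard normal prior; the `beta` weight imposes an information
#' bottleneck on the latent code. Optimized full batch with Adam via the
#' reparameterization trick.
#'
#' @param images List of `H x W x 3` arrays (or a single array).
#' @param spec A `bvae_spec`.
#' @return A `bvae` model with weight matrices, the `spec`, the per-epoch
#'   total loss trace (`loss`), and its reconstruction/KL components
#'   (`recon`, `kl`).
#' @export
train_bvae <- function(images, spec = bvae_spec()) {
  X <- images_to_matrix(images)
  if (is.null(X) || nrow(X) == 0L) stop("empty training set")
  set.seed(spec$seed)
  n <- nrow(X); D <- ncol(X); H <- spec$hidden; L <- spec$latent_dim
  rn <- function(p, q, sd) matrix(stats::rnorm(p * q, sd = sd), p, q)
  w <- list(W1 = rn(D, H, sqrt(1 / D)), b1 = rep(0, H),
            W2 = rn(H, L, sqrt(1 / H)), b2 = rep(0, L),
            W3 = matrix(0, H, L),       b3 = rep(0, L),   # logvar head at 0
            W4 = rn(L, H, sqrt(1 / L)), b4 = rep(0, H),
            W5 = rn(H, D, sqrt(1 / H)), b5 = rep(0, D))
  m <- lapply(w, function(x) x * 0); v <- m; t_adam <- 0L
  loss_tr <- recon_tr <- kl_tr <- numeric(spec$epochs)
  sig <- function(z) 1 / (1 + exp(-z))
  for (ep in seq_len(spec$epochs)) {
    h <- tanh(sweep(X %*% w$W1, 2L, w$b1, `+`))
    mu <- sweep(h %*% w$W2, 2L, w$b2, `+`)
    lv <- sweep(h %*% w$W3, 2L, w$b3, `+`)
    epsm <- matrix(stats::rnorm(n * L), n, L)
    z <- mu + epsm * exp(lv / 2)
    g <- tanh(sweep(z %*% w$W4, 2L, w$b4, `+`))
    xh <- sig(sweep(g %*% w$W5, 2L, w$b5, `+`))
    recon <- sum((xh - X)^2) / n
    kl <- 0.5 * sum(exp(lv) + mu^2 - 1 - lv) / n
    loss_tr[ep] <- recon + spec$beta * kl
    recon_tr[ep] <- recon; kl_tr[ep] <- kl
    # backward
    d5 <- (2 * (xh - X) / n) * xh * (1 - xh)
    gW5 <- crossprod(g, d5); gb5 <- colSums(d5)
    dg <- d5 %*% t(w$W5)
    d4 <- dg * (1 - g^2)
    gW4 <- crossprod(z, d4); gb4 <- colSums(d4)
    dz <- d4 %*% t(w$W4)
    dmu <- dz + (spec$beta / n) * mu
    dlv <- dz * epsm * 0.5 * exp(lv / 2) + (spec$beta / n) * 0.5 * (exp(lv) - 1)
    gW2 <- crossprod(h, dmu); gb2 <- colSums(dmu)
    gW3 <- crossprod(h, dlv); gb3 <- colSums(dlv)
    dh <- dmu %*% t(w$W2) + dlv %*% t(w$W3)
    d1 <- dh * (1 - h^2)
    gW1 <- crossprod(X, d1); gb1 <- colSums(d1)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
                  W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5)
    t_adam <- t_adam + 1L
    for (nm in names(w)) {
      up <- adam_update(w[[nm]], grads[[nm]], m[[nm]], v[[nm]], t_adam,
                        spec$lr)
      w[[nm]] <- up$x; m[[nm]] <- up$m; v[[nm]] <- up$v
    }
  }
  structure(list(weights = w, spec = spec, input_dim = D,
                 loss = loss_tr, recon = recon_tr, kl = kl_tr),
            class = "bvae")
}

#' Encode an image to its latent posterior
#'
#' Runs the trained encoder deterministically (no latent sampling) and returns
#' the diagonal-Gaussian posterior parameters.
#'
#' @param model A trained `bvae`.
#' @param image `H x W x 3` array with the training image shape.
#' @return A [gaussian_representation()] of dimension `latent_dim`.
#' @export
bvae_encode <- function(model, image) {
  x <- as.numeric(image)
  if (length(x) != model$input_dim) stop("image shape mismatch")
  w <- model$weights
  h <- tanh(x %*% w$W1 + matrix(w$b1, 1L))
  mu <- as.numeric(h %*% w$W2) + w$b2
  lv <- as.numeric(h %*% w$W3) + w$b3
  gaussian_representation(mu, lv)
}

# ---------------------------------------------------------------------------
# Synthetic email corpus

email_feature_names <- c("mismatched_sender", "requesting_credentials",
                         "urgent_language", "making_offer",
                         "suspicious_subject", "link_mismatch")

#' Generate a synthetic phishing/ham email corpus
#'
#' Stands in for an expert-coded email corpus with language-model embeddings.
#' Each email carries six binary expert features (mismatched sender,
#' requesting credentials, urgent language, making an offer, suspicious
#' subject, link mismatch), a ham/phishing label, and an embedding generated
#' by a linear latent-factor model: `embedding = W [features, latent] + noise`
#' with `W` fixed by the seed. Each feature's incidence is higher under
#' phishing than ham by `effect_strength`, so embeddings are statistically
#' more similar (higher cosine) within class than between classes.
#'
#' @param n Number of emails.
#' @param embedding_dim Embedding length (1536 mirrors the language-model
#'   embeddings of the phishing study; smaller values run faster).
#' @param phishing_fraction Fraction of phishing labels, in (0, 1).
#' @param effect_strength Per-feature incidence difference phishing - ham.
#' @param noise_sd Standard deviation of the additive embedding noise.
#' @param base_rate Feature incidence under ham.
#' @param latent_dim Label-free latent factors mixed into the embedding.
#' @param seed Integer seed; the corpus is fully reproducible given it.
#' @return A list with `features` (n x 6 binary matrix), `label` (character,
#'   `"ham"`/`"phishing"`), `embeddings` (n x embedding_dim matrix), and
#'   `text` (stub strings).
#' @export
generate_synthetic_emails <- function(n, embedding_dim = 1536L,
                                      phishing_fraction = 0.5,
                                      effect_strength = 0.4,
                                      noise_sd = 0.1, base_rate = 0.2,
                                      latent_dim = 4L, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (phishing_fraction <= 0 || phishing_fraction >= 1)
    stop("phishing_fraction must be in (0, 1)")
  set.seed(seed)
  k <- length(email_feature_names)
  W <- matrix(stats::rnorm((k + latent_dim) * embedding_dim),
              k + latent_dim, embedding_dim)
  n_phish <- round(n * phishing_fraction)
  label <- sample(c(rep("phishing", n_phish), rep("ham", n - n_phish)))
  p_feat <- ifelse(label == "phishing", base_rate + effect_strength, base_rate)
  p_feat <- pmin(pmax(p_feat, 0), 1)
  features <- sapply(seq_len(k), function(j)
    stats::rbinom(n, 1L, p_feat))
  colnames(features) <- email_feature_names
  latent <- matrix(stats::rnorm(n * latent_dim), n, latent_dim)
  signal <- cbind(features - 0.5, latent)
  embeddings <- signal %*% W +
    matrix(stats::rnorm(n * embedding_dim, sd = noise_sd), n, embedding_dim)
  text <- sprintf("email %03d [%s]", seq_len(n), label)
  list(features = features, label = label, embeddings = embeddings,
       text = text)
}

#' File-backed embedding provider
#'
#' Builds a lookup function `id -> embedding` from a delimited file
#' (first column the id, remaining columns the vector) or a JSON file
#' (an object mapping id to a numeric array). Use this to supply real
#' embedding vectors instead of the synthetic generator.
#'
#' @param path Path to a CSV/TSV or JSON file.
#' @return A function mapping a character id to a numeric embedding.
#' @export
embedding_provider_file <- function(path) {
  table <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(raw, as.numeric)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          sep = if (grepl("\\.tsv$", path)) "\t" else ",")
    stats::setNames(lapply(seq_len(nrow(df)),
                           function(i) as.numeric(df[i, -1L])),
                    as.character(df[[1L]]))
  }
  function(id) {
    v <- table[[as.character(id)]]
    if (is.null(v)) stop("no embedding for id '", id, "'")
    v
  }
}
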
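#' Split patients into training and testing sets
#'
#' Partitioning is at the patient level (never the tile level), so every
#' slide and tile of a patient lands on exactly one side. Reproducible per
#' seed; both sides are always non-empty.
#'
#' @param patients Character vector of unique patient ids.
#' @param ratio Training fraction in (0, 1); the published design uses 4:1,
#'   i.e. 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` character vectors (disjoint,
#'   exhaustive).
#' @export
split_patients <- function(patients, ratio = 0.8, seed = 1L) {
  patients <- unique(as.character(patients))
  n <- length(patients)
  if (n < 2L) stop("invalid input: need at least 2 patients", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)", call. = FALSE)
  n_train <- min(max(round(ratio * n), 1L), n - 1L)
  idx <- with_local_seed(seed, sample.int(n, n_train))
  list(train = patients[sort(idx)], test = patients[sort(setdiff(seq_len(n), idx))])
}

adam_init <- function(W) {
  list(m = zero_like(W), v = zero_like(W), t = 0L)
}

adam_step <- function(W, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(W)) {
    g <- grads[[nm]] + weight_decay * W[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    W[[nm]] <- W[[nm]] - lr * (state$m[[nm]] / b1t) /
      (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(W = W, state = state)
}

# Coerce a tile collection to an N x s x s x 3 array at the trainer's
# augmentation resolution, block-mean downscaling once up front.
as_training_array <- function(tiles, input_size) {
  if (is.array(tiles) && length(dim(tiles)) == 4L) {
    if (dim(tiles)[2] == input_size && dim(tiles)[3] == input_size) return(tiles)
    n <- dim(tiles)[1]
    out <- array(0, c(n, input_size, input_size, 3))
    for (i in seq_len(n))
      out[i, , , ] <- pool_blocks(tiles[i, , , , drop = TRUE], input_size)
    return(out)
  }
  if (is.list(tiles)) {
    n <- length(tiles)
    out <- array(0, c(n, input_size, input_size, 3))
    for (i in seq_len(n)) {
      px <- as_pixels(tiles[[i]])
      out[i, , , ] <- if (dim(px)[1] == input_size && dim(px)[2] == input_size)
        px else pool_blocks(px, input_size)
    }
    return(out)
  }
  stop("invalid input: tiles must be a 4-d array or a list of tiles", call. = FALSE)
}

#' Train a DL-CC model
#'
#' Seeded optimization of the total objective: for each epoch, every tile
#' contributes one augmented view pair; each mini-batch's pair is encoded by
#' the shared-weight model, the three loss components are computed and an
#' Adam step is taken. Per-epoch mean losses are logged. Fully
#' deterministic for a fixed seed.
#'
#' @param tiles Tile set: an `N x s x s x 3` array, or a list of
#'   `tile_record`s / pixel arrays. Tiles are block-mean downscaled once to
#'   `config$input_size` and augmented at that resolution.
#' @param config A [dlcc_desk_config()]-style `dlcc_config`.
#' @param epochs Number of passes over the tile set.
#' @param batch_size Mini-batch size (>= 2; batch variance is required by
#'   the representation loss). Needs at least `2 * batch_size` tiles.
#' @param learning_rate,weight_decay Adam settings (defaults 3e-4, 1e-5).
#' @param seed Integer seed covering initialization, shuffling and
#'   augmentation.
#' @param augmentations Operator subset used for view pairs.
#' @param params Augmentation parameter ranges.
#' @param verbose Print per-epoch losses.
#' @return List with the trained `model` and a per-epoch loss `log`
#'   (`data.frame`: epoch, instance, cluster, representation, total).
#' @export
dlcc_train <- function(tiles, config, epochs = 20L, batch_size = 128L,
                       learning_rate = 3e-4, weight_decay = 1e-5,
                       seed = 1L, augmentations = config$augmentations,
                       params = augment_params(), verbose = FALSE) {
  if (batch_size < 2L) stop("batch_size must be >= 2", call. = FALSE)
  imgs <- as_training_array(tiles, config$input_size)
  n <- dim(imgs)[1]
  if (n < 2L * batch_size)
    stop("need at least 2 * batch_size tiles (got ", n, ")", call. = FALSE)

  model <- dlcc_init(config, seed = derive_seed(seed, 0L))
  state <- adam_init(model$weights)
  g <- config$pool_grid
  p <- 3L * g^2
  log_rows <- vector("list", epochs)

  with_local_seed(derive_seed(seed, 1L), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      n_batches <- n %/% batch_size
      ep_losses <- matrix(0, n_batches, 4)
      for (b in seq_len(n_batches)) {
        idx <- perm[((b - 1L) * batch_size + 1L):(b * batch_size)]
        pair_seeds <- sample.int(2147483646L, length(idx))
        xa <- matrix(0, length(idx), p)
        xb <- matrix(0, length(idx), p)
        for (i in seq_along(idx)) {
          img <- imgs[idx[i], , , , drop = TRUE]
          pr <- make_pair(img, pair_seeds[i], ops = augmentations, params = params)
          xa[i, ] <- as.vector(pool_blocks(pr$view_a, g)) - 0.5
          xb[i, ] <- as.vector(pool_blocks(pr$view_b, g)) - 0.5
        }
        bg <- dlcc_batch_grad(model, xa, xb)
        comp <- unlist(bg$losses)
        if (!all(is.finite(comp))) {
          bad <- names(bg$losses)[!vapply(bg$losses, is.finite, logical(1))]
          stop("training diverged at epoch ", ep, ", batch ", b,
               ": non-finite loss component(s): ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        ep_losses[b, ] <- comp
        upd <- adam_step(model$weights, bg$grads, state,
                         learning_rate, weight_decay)
        model$weights <- upd$W
        state <- upd$state
      }
      mu <- colMeans(ep_losses)
      log_rows[[ep]] <- data.frame(epoch = ep, instance = mu[1], cluster = mu[2],
                                   representation = mu[3], total = mu[4])
      if (verbose)
        message(sprintf("epoch %3d  inst %.4f  clus %.4f  rep %.4f  total %.4f",
                        ep, mu[1], mu[2], mu[3], mu[4]))
    }
  })
  model$trained <- TRUE
  list(model = model, log = do.call(rbind, log_rows))
}

#' Save a DL-CC checkpoint
#'
#' Serializes the model (configuration, weights, seed) as a single portable
#' JSON file.
#'
#' @param model A `dlcc_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  w <- lapply(model$weights, function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.vector(x))
    else list(dim = length(x), data = as.vector(x))
  })
  obj <- list(format = "pathoclust-dlcc-1",
              config = unclass(model$config),
              seed = model$seed, trained = model$trained, weights = w)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a DL-CC checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `dlcc_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "pathoclust-dlcc-1")
    stop("not a pathoclust checkpoint: ", path, call. = FALSE)
  cfg <- do.call(dlcc_config, obj$config[setdiff(names(obj$config), character())])
  weights <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2]) else as.numeric(w$data)
  })
  structure(list(config = cfg, weights = weights, seed = obj$seed,
                 trained = isTRUE(obj$trained)), class = "dlcc_model")
}
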
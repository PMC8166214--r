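#' Training configuration
#'
#' @param learning_rates vector of per-phase learning rates.
#' @param epochs vector of per-phase epoch counts (same length).
#' @param batch_size minibatch size (default 64).
#' @param split train fraction of the train/validation split.
#' @param seed integer; fixes initialization, the split and shuffling.
#' @return list of validated settings.
#' @export
train_config <- function(learning_rates, epochs, batch_size = 64,
                         split = 0.75, seed = 1) {
  stopifnot(length(learning_rates) == length(epochs), all(epochs > 0),
            split > 0, split < 1, batch_size >= 2)
  list(learning_rates = learning_rates, epochs = epochs,
       batch_size = batch_size, split = split, seed = seed)
}

# stratified train/validation split; every class lands in the train set
stratified_split <- function(y, split) {
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1, round(length(idx) * split))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

run_phases <- function(net, X, y, cfg, X_val, y_val) {
  trace <- data.frame()
  for (ph in seq_along(cfg$epochs)) {
    res <- mlp_train_phase(net, X, y, epochs = cfg$epochs[ph],
                           lr = cfg$learning_rates[ph],
                           batch_size = cfg$batch_size,
                           X_val = X_val, y_val = y_val)
    net <- res$net
    res$trace$phase <- ph
    trace <- rbind(trace, res$trace)
  }
  list(net = net, trace = trace)
}

#' Train the cell-level type classifier
#'
#' A feed-forward network mapping harmonized cell expression to type
#' probabilities: three hidden layers of width 3m (m = number of marker
#' genes), tanh activations, batch normalization on every layer, an L1
#' weight penalty of 1e-4, and a softmax output over the k types. Trained
#' with Adam (Xavier init, batch size 64, cross-entropy) in two phases of
#' 20 epochs at learning rates 5e-3 then 5e-4, on a stratified 75/25
#' train/validation split.
#'
#' @param E_ref harmonized reference matrix (cells x genes); apply
#'   [harmonize_expression()] first.
#' @param T_ref per-cell type labels.
#' @param cfg a [train_config()]; the default reproduces the schedule above.
#' @return a `jsta_cell_classifier`: the fitted network, the type levels,
#'   the gene names, and per-epoch train/validation loss and accuracy.
#' @export
train_cell_classifier <- function(E_ref, T_ref,
                                  cfg = train_config(c(5e-3, 5e-4), c(20, 20),
                                                     split = 0.75)) {
  E_ref <- as.matrix(E_ref)
  types <- sort(unique(as.character(T_ref)))
  y <- match(as.character(T_ref), types)
  counts <- tabulate(y, length(types))
  if (any(counts < 2))
    stopf("every type needs at least 2 cells; offending: %s",
          paste(types[counts < 2], collapse = ", "))
  m <- ncol(E_ref)
  with_seed(cfg$seed, {
    tr <- stratified_split(y, cfg$split)
    net <- mlp_init(m, rep(3 * m, 3), length(types),
                    penalty = "l1", lambda = 1e-4)
    fit <- run_phases(net, E_ref[tr, , drop = FALSE], y[tr], cfg,
                      E_ref[!tr, , drop = FALSE], y[!tr])
    structure(list(net = fit$net, types = types, genes = colnames(E_ref),
                   trace = fit$trace),
              class = "jsta_cell_classifier")
  })
}

#' Classify cells from their expression
#'
#' @param classifier a [train_cell_classifier()] result.
#' @param E_c harmonized cells x genes matrix (same gene panel and
#'   harmonization as the reference).
#' @return list with `P_c` (cells x types probability matrix) and `T_c`
#'   (type per cell; argmax, ties to the lowest type index).
#' @export
classify_cells <- function(classifier, E_c) {
  E_c <- as.matrix(E_c)
  if (ncol(E_c) != length(classifier$genes))
    stopf("gene panel mismatch: classifier trained on %d genes, got %d",
          length(classifier$genes), ncol(E_c))
  if (!is.null(colnames(E_c)) &&
      !identical(colnames(E_c), classifier$genes))
    stopf("gene panel mismatch: column names differ from training genes")
  P_c <- mlp_forward(classifier$net, E_c)$P
  colnames(P_c) <- classifier$types
  T_c <- classifier$types[max.col(P_c, ties.method = "first")]
  list(P_c = P_c, T_c = T_c)
}

#' Train (or warm-retrain) the pixel-level type classifier
#'
#' A feed-forward network mapping per-pixel marker densities to type
#' probabilities: three hidden layers of widths (2m, 4m, 8m) — each layer
#' twice the size of the last — tanh activations, batch normalization, an
#' L2 penalty of 1e-3 on all weights including the output layer, softmax
#' over the k types. Inputs are log1p-transformed densities z-scored per
#' gene with statistics frozen at the first (cold) training call, so
#' warm-started retraining sees a fixed feature scale. Cold starts train
#' two phases (25 epochs at 1e-3, 25 at 1e-4); warm restarts keep the
#' previous weights and train 15 epochs at 1e-4, on a fresh pixel sample.
#'
#' @param E_p_sample raw density rows for the sampled pixels (pixels x
#'   marker genes).
#' @param types_sample current cell type of each sampled pixel's cell.
#' @param types the full type level set (so the output dimension is stable
#'   across retraining even if a type temporarily has no pixels).
#' @param cfg a [train_config()]; defaults depend on warm/cold start.
#' @param warm_start optional previous `jsta_pixel_classifier` to retrain.
#' @return a `jsta_pixel_classifier` with the fitted network, frozen
#'   normalization statistics, type levels, and training traces.
#' @export
train_pixel_classifier <- function(E_p_sample, types_sample, types = NULL,
                                   cfg = NULL, warm_start = NULL) {
  E_p_sample <- as.matrix(E_p_sample)
  if (!all(is.finite(E_p_sample))) stopf("densities must be finite")
  types_sample <- as.character(types_sample)
  if (length(unique(types_sample)) < 2)
    stopf("need at least 2 types among the sampled pixels")
  if (is.null(types))
    types <- if (is.null(warm_start)) sort(unique(types_sample))
             else warm_start$types
  if (!all(types_sample %in% types)) stopf("sample contains unknown types")
  y <- match(types_sample, types)
  m <- ncol(E_p_sample)

  if (is.null(warm_start)) {
    if (is.null(cfg)) cfg <- train_config(c(1e-3, 1e-4), c(25, 25), split = 0.8)
    lg <- log1p(E_p_sample)
    norm_mean <- colMeans(lg)
    norm_sd <- apply(lg, 2, sd)
    norm_sd[norm_sd == 0 | is.na(norm_sd)] <- 1
  } else {
    if (is.null(cfg)) cfg <- train_config(1e-4, 15, split = 0.8)
    norm_mean <- warm_start$norm_mean
    norm_sd <- warm_start$norm_sd
  }
  X <- normalize_densities(E_p_sample, norm_mean, norm_sd)

  with_seed(cfg$seed, {
    # classes with one sampled pixel go entirely to the train side
    tr <- stratified_split(y, cfg$split)
    if (sum(!tr) < 2) tr[sample(which(tr), 2)] <- FALSE
    net <- if (is.null(warm_start)) {
      mlp_init(m, c(2 * m, 4 * m, 8 * m), length(types),
               penalty = "l2", lambda = 1e-3, penalize_output = TRUE)
    } else {
      warm_start$net
    }
    fit <- run_phases(net, X[tr, , drop = FALSE], y[tr], cfg,
                      X[!tr, , drop = FALSE], y[!tr])
    structure(list(net = fit$net, types = types,
                   norm_mean = norm_mean, norm_sd = norm_sd,
                   trace = fit$trace, genes = colnames(E_p_sample)),
              class = "jsta_pixel_classifier")
  })
}

normalize_densities <- function(E_p, norm_mean, norm_sd) {
  sweep(sweep(log1p(E_p), 2, norm_mean, "-"), 2, norm_sd, "/")
}

#' Per-pixel cell type probabilities
#'
#' Applies the frozen normalization and the trained pixel network.
#'
#' @param classifier a [train_pixel_classifier()] result.
#' @param E_p_rows raw density rows (pixels x marker genes).
#' @return pixels x types probability matrix.
#' @export
pixel_type_probabilities <- function(classifier, E_p_rows) {
  E_p_rows <- as.matrix(E_p_rows)
  if (!all(is.finite(E_p_rows))) stopf("densities must be finite")
  X <- normalize_densities(E_p_rows, classifier$norm_mean, classifier$norm_sd)
  P <- mlp_forward(classifier$net, X)$P
  colnames(P) <- classifier$types
  P
}
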
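#' Classify a heterogeneous particle stack
#'
#' Runs Steps 1-3 of the workflow on a stack: preprocessing (64x64 Fourier
#' crop, per-image normalisation, channel replication for the residual
#' model), autoencoder feature extraction, UMAP reduction to 2D, SNN graph
#' construction with adaptive k, and normalized spectral clustering into
#' `k_classes` groups. `model = "raw"` skips the autoencoder and embeds the
#' flattened preprocessed images directly (the baseline the learned features
#' are compared against). Per-stage seeds derive from the master seed, so
#' e.g. changing UMAP settings leaves training untouched.
#'
#' @param stack a `cryo_stack`.
#' @param k_classes number of structures K (assumed known).
#' @param model `"mlp"`, `"res"` or `"raw"`.
#' @param seed master seed.
#' @param epochs training epochs; `NULL` uses the model default (500 mlp,
#'   1 res).
#' @param ns shared-neighbour threshold NS (default 5).
#' @param umap_neighbors,umap_min_dist,umap_epochs UMAP parameters.
#' @param verbose print stage progress.
#' @return An object of class `cryo_classification`: `clusters`,
#'   `embedding`, `graph`, `latents`, `model` (the trained autoencoder or
#'   NULL), and an `accuracy` report when the stack carries ground truth.
#' @export
classify_particle_stack <- function(stack, k_classes,
                                    model = c("mlp", "res", "raw"),
                                    seed = 1, epochs = NULL, ns = 5,
                                    umap_neighbors = 15, umap_min_dist = 0.1,
                                    umap_epochs = 300, verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(stack, "cryo_stack"))
  say <- function(...) if (verbose) message(sprintf(...))
  channels <- if (model == "res") 3 else 1
  target <- min(64L, dim(stack$images)[1])
  if (model != "raw" && target < 64L)
    stop("autoencoder models require projection images of at least 64x64")
  say("[preprocess] downsampling to %dx%d, %d channel(s)", target, target,
      channels)
  pre <- preprocess_stack(stack, channels = channels, target = target)
  trained <- NULL
  if (model == "raw") {
    say("[features] raw-image baseline (no autoencoder)")
    n <- dim(pre$images)[4]
    npix <- prod(dim(pre$images)[1:2])
    latents <- t(matrix(pre$images[, , 1, ], nrow = npix, ncol = n))
  } else {
    cfg <- training_config(model, max_epochs = epochs,
                           seed = derive_seed(seed, "train"))
    net <- if (model == "mlp") build_ae_mlp(seed = cfg$seed)
           else build_ae_res(seed = cfg$seed)
    say("[train] %s autoencoder, %d epoch(s)", model, cfg$max_epochs)
    trained <- train_autoencoder(net, pre, cfg)
    say("[train] final epoch loss %.5f", tail(trained$loss_history, 1))
    latents <- extract_latents(trained, pre)
  }
  say("[umap] reducing %d x %d latents to 2D", nrow(latents), ncol(latents))
  emb <- reduce_umap_2d(latents, seed = derive_seed(seed, "umap"),
                        n_neighbors = umap_neighbors,
                        min_dist = umap_min_dist, n_epochs = umap_epochs)
  k <- adaptive_k(nrow(emb$points), ns)
  say("[snn] k = %d (adaptive), NS = %d", k, ns)
  graph <- build_snn_graph(emb, NS = ns, k = k)
  clusters <- spectral_cluster(graph, K = k_classes,
                               seed = derive_seed(seed, "cluster"))
  accuracy <- NULL
  if (!is.null(stack$labels_true)) {
    accuracy <- match_labels_accuracy(clusters, stack$labels_true)
    say("[evaluate] matched accuracy %.2f%%", 100 * accuracy$overall)
  }
  structure(list(clusters = clusters, embedding = emb, graph = graph,
                 latents = latents, model = trained, model_kind = model,
                 accuracy = accuracy, seed = seed, k_classes = k_classes),
            class = "cryo_classification")
}

#' @export
print.cryo_classification <- function(x, ...) {
  cat(sprintf("<cryo_classification> model=%s K=%d N=%d\n", x$model_kind,
              x$k_classes, length(x$clusters$labels)))
  if (!is.null(x$accuracy))
    cat(sprintf("  matched accuracy: %.2f%%\n", 100 * x$accuracy$overall))
  invisible(x)
}

#' Run the full heterogeneous-reconstruction pipeline
#'
#' Steps 1-4 end to end: simulate (or accept) a heterogeneous stack,
#' classify it, then reconstruct a density map from each predicted group
#' using the recorded orientations, and score each map against its matched
#' reference volume by FSC.
#'
#' @param stack a `cryo_stack` with orientations (required for Step 4).
#' @param k_classes number of structures.
#' @param references optional list of `cryo_volume` ground-truth maps; when
#'   given (and ground-truth labels exist) each reconstruction is FSC-scored
#'   against the reference its cluster was matched to.
#' @param model,seed,epochs,... passed to [classify_particle_stack()].
#' @param reconstruct_size volume size for the reconstructions (default:
#'   image size).
#' @return A `cryo_pipeline_result`: the classification plus
#'   `reconstructions` (list of volumes per cluster) and `fsc` (list of FSC
#'   curves, when references were given).
#' @export
run_hetero_pipeline <- function(stack, k_classes, references = NULL,
                                model = "mlp", seed = 1, epochs = NULL,
                                reconstruct_size = NULL, ...) {
  cls <- classify_particle_stack(stack, k_classes, model = model,
                                 seed = seed, epochs = epochs, ...)
  recons <- vector("list", k_classes)
  fscs <- NULL
  if (!is.null(stack$orientations)) {
    for (g in seq_len(k_classes) - 1L) {
      subset <- which(cls$clusters$labels == g)
      if (length(subset) == 0) next
      recons[[g + 1L]] <- backproject_reconstruct(stack, subset,
                                                  size = reconstruct_size)
    }
    if (!is.null(references) && !is.null(cls$accuracy)) {
      fscs <- vector("list", k_classes)
      perm <- cls$accuracy$permutation  # cluster id -> matched class id
      for (g in seq_len(k_classes) - 1L) {
        cls_id <- perm[as.character(g)]
        if (is.na(cls_id) || is.null(recons[[g + 1L]])) next
        ref <- references[[cls_id + 1L]]
        rec <- recons[[g + 1L]]
        if (dim(ref$grid)[1] != dim(rec$grid)[1]) next
        fscs[[g + 1L]] <- fsc_curve(rec, ref)
      }
    }
  }
  out <- c(unclass(cls), list(reconstructions = recons, fsc = fscs))
  class(out) <- c("cryo_pipeline_result", "cryo_classification")
  out
}
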
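## Feature-map extraction and class-activation heatmaps.

#' Feature maps from named stages of the network
#'
#' Evaluation-mode forward pass capturing activations. Convolutional stages
#' are addressed by structural path (`"block1"`, `"block2"`, `"block3"`);
#' `"transformer"` returns the final token sequence. Only the first
#' `n_filters` channels are returned for the conv stages (display
#' convention).
#'
#' @param model An `rtn_model` or fitted `restransnet` object.
#' @param x A single image matrix.
#' @param layers Character vector of stage selectors.
#' @param n_filters Number of leading filters to keep per conv stage.
#' @return Named list; conv stages as arrays `(h, w, n_filters)`,
#'   `"transformer"` as the `(n_tokens x d)` output sequence.
#' @export
feature_maps <- function(model, x, layers = c("block1", "block2", "block3",
                                              "transformer"),
                         n_filters = 4L) {
  model <- as_rtn_model(model)
  fw <- rtn_forward(model, x, train = FALSE, capture = TRUE)
  cfg <- model$config
  out <- list()
  for (ly in layers) {
    if (ly == "transformer") {
      out$transformer <- fw$maps$tokens
    } else if (grepl("^block[123]$", ly)) {
      i <- as.integer(sub("block", "", ly))
      Ci <- cfg$channels[i]
      side <- cfg$img_size %/% 2L^i
      k <- min(n_filters, Ci)
      wide <- matrix(fw$maps$backbone[[i]][, 1], Ci, side * side)
      arr <- array(0, dim = c(side, side, k))
      for (f in seq_len(k)) arr[, , f] <- matrix(wide[f, ], side, side)
      out[[ly]] <- arr
    } else stop("unknown layer selector: ", ly)
  }
  out
}

## map a patch-level weight vector to an upsampled [0,1] heatmap
attention_to_heatmap <- function(att, grid, size) {
  hm <- resize_bilinear(matrix(att, grid, grid), size, size)
  rng <- range(hm)
  if (rng[2] > rng[1]) (hm - rng[1]) / (rng[2] - rng[1]) else hm * 0
}

#' Class-activation heatmap from transformer attention
#'
#' The class-token-to-patch attention of the last transformer block,
#' averaged over heads, reshaped to the patch grid and bilinearly upsampled
#' to the input resolution, then min-max normalized to \[0, 1\]. With
#' `rollout = TRUE` attention is instead propagated through all blocks
#' (attention rollout: per block, the head-averaged attention mixed with the
#' identity and row-normalized, then accumulated by matrix product).
#'
#' @param model An `rtn_model` or fitted `restransnet` object.
#' @param x A single image matrix.
#' @param rollout Use attention rollout across all blocks.
#' @return Matrix `(img_size x img_size)` in \[0, 1\].
#' @export
class_activation_map <- function(model, x, rollout = FALSE) {
  model <- as_rtn_model(model)
  fw <- rtn_forward(model, x, train = FALSE, capture = TRUE)
  cfg <- model$config
  nt <- cfg$n_patches + 1L
  head_avg <- function(Ai) Reduce(`+`, Ai) / length(Ai)
  if (!rollout) {
    A <- head_avg(fw$maps$attn[[cfg$n_blocks]][[1]])
    att <- A[1, -1]
  } else {
    R <- diag(nt)
    for (j in seq_len(cfg$n_blocks)) {
      A <- head_avg(fw$maps$attn[[j]][[1]])
      A <- 0.5 * A + 0.5 * diag(nt)
      A <- A / rowSums(A)
      R <- A %*% R
    }
    att <- R[1, -1]
  }
  attention_to_heatmap(att, cfg$patch_grid, cfg$img_size)
}
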
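# Network architectures built on the engine in nn-engine.R.

#' Build a ResNet-20-style classifier for 4-channel tiles
#'
#' The trunk follows the classic 20-layer residual design for small images:
#' three stages of three basic blocks at 16/32/64 filters. The stem is
#' adapted for 4-channel multiphoton tiles and larger tile sizes with a
#' stride-2 convolution followed by 2x2 max-pooling. The head is a 1x1
#' convolutional projection to 512 channels, batch-norm, ReLU, global average
#' pooling (the 512-d penultimate feature) and a single linear cancer-logit
#' neuron. Because pooling is global the same network accepts any tile size
#' that survives the four halvings, and the GAP + linear head is exactly the
#' structure class activation mapping requires.
#'
#' @param seed integer seed controlling weight initialisation.
#' @return an object of class `mphisto_model`.
#' @export
resnet20 <- function(seed = 1L) {
  set.seed(seed)
  g <- nn_graph()
  g <- nn_add(g, "input"); x <- g$last

  conv_bn_relu <- function(g, from, cin, cout, k = 3L, stride = 1L) {
    g <- nn_conv(g, from, cin, cout, k, stride); g <- nn_bn(g, g$last, cout)
    nn_relu(g, g$last)
  }

  # stem: 4 -> 16, spatial /4
  g <- conv_bn_relu(g, x, 4L, 16L, stride = 2L)
  g <- nn_maxpool(g, g$last)

  block <- function(g, from, cin, cout, stride) {
    g <- nn_conv(g, from, cin, cout, 3L, stride); g <- nn_bn(g, g$last, cout)
    g <- nn_relu(g, g$last)
    g <- nn_conv(g, g$last, cout, cout, 3L, 1L); g <- nn_bn(g, g$last, cout)
    main <- g$last
    if (stride != 1L || cin != cout) {
      g <- nn_conv(g, from, cin, cout, 1L, stride); g <- nn_bn(g, g$last, cout)
      from <- g$last
    }
    g <- nn_addn(g, main, from)
    nn_relu(g, g$last)
  }

  widths <- c(16L, 32L, 64L)
  cin <- 16L
  for (s in seq_along(widths)) {
    for (b in 1:3) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      g <- block(g, g$last, cin, widths[s], stride)
      cin <- widths[s]
    }
  }

  # CAM head: 1x1 projection to 512 maps, then GAP and one linear neuron
  g <- nn_conv(g, g$last, 64L, 512L, k = 1L); g <- nn_bn(g, g$last, 512L)
  g <- nn_relu(g, g$last); cam_node <- g$last
  g <- nn_gap(g, g$last); feat_node <- g$last
  # zero-initialised head: an untrained model predicts p = 0.5 exactly
  g <- nn_dense(g, g$last, 512L, 1L, init = "zero")

  structure(list(net = g, arch = "resnet20", in_channels = 4L,
                 cam_node = cam_node, feat_node = feat_node,
                 logit_node = g$last, trained = FALSE, log = NULL),
            class = "mphisto_model")
}

#' Build a U-Net-style encoder-decoder for adipocyte segmentation
#'
#' Depth-3 encoder-decoder with skip connections: two down-sampling levels,
#' a bottleneck, and mirrored nearest-neighbour up-sampling with channel
#' concatenation, ending in a 1x1 convolution emitting a per-pixel lipid
#' logit at the input resolution.
#'
#' @param base base filter count at the first level (doubled per depth).
#' @param seed integer seed controlling weight initialisation.
#' @return an object of class `mphisto_segmenter`.
#' @export
unet <- function(base = 8L, seed = 1L) {
  set.seed(seed)
  g <- nn_graph()
  g <- nn_add(g, "input"); x <- g$last
  cbr <- function(g, from, cin, cout) {
    g <- nn_conv(g, from, cin, cout, 3L, 1L); g <- nn_bn(g, g$last, cout)
    nn_relu(g, g$last)
  }
  g <- cbr(g, x, 4L, base); e1 <- g$last
  g <- nn_maxpool(g, e1)
  g <- cbr(g, g$last, base, 2L * base); e2 <- g$last
  g <- nn_maxpool(g, e2)
  g <- cbr(g, g$last, 2L * base, 4L * base)
  g <- nn_upsample(g, g$last)
  g <- nn_concat(g, g$last, e2)
  g <- cbr(g, g$last, 6L * base, 2L * base)
  g <- nn_upsample(g, g$last)
  g <- nn_concat(g, g$last, e1)
  g <- cbr(g, g$last, 3L * base, base)
  g <- nn_conv(g, g$last, base, 1L, k = 1L)

  structure(list(net = g, arch = "unet", in_channels = 4L, depth = 3L,
                 base = base, trained = FALSE, log = NULL),
            class = "mphisto_segmenter")
}

# Forward pass returning logits (and optionally intermediate activations).
model_forward <- function(model, x, train = FALSE, keep = integer()) {
  fw <- nn_forward(model$net, x, train = train)
  kept <- if (length(keep)) fw$acts[keep] else NULL
  list(fw = fw, logits = fw$out, kept = kept)
}

#' @export
print.mphisto_model <- function(x, ...) {
  cat("<mphisto_model> arch:", x$arch,
      "| nodes:", length(x$net$nodes),
      "| trained:", x$trained, "\n")
  invisible(x)
}

#' @export
print.mphisto_segmenter <- function(x, ...) {
  cat("<mphisto_segmenter> depth:", x$depth, "base:", x$base,
      "| trained:", x$trained, "\n")
  invisible(x)
}
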
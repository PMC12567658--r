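# Architecture auditing: exact trainable-parameter enumeration and analytic
# FLOP counting (2 x multiply-accumulates for all conv/linear operations at a
# stated input size, fused-normalisation convention, batch 1).

#' Count trainable parameters of a detector or module
#'
#' Enumerates every trainable scalar in the module tree. The per-submodule
#' breakdown sums exactly to the total.
#'
#' @param g a detector or any module.
#' @return an `lmtb_arch_stats` object: `total` (exact integer),
#'   `millions`, and a `breakdown` data frame over top-level submodules.
#' @export
count_parameters <- function(g) {
  stopifnot(inherits(g, "lmtb_module"))
  by <- vapply(g$children, n_params, numeric(1))
  own <- sum(vapply(g$params, function(p) length(p$v), numeric(1)))
  if (own > 0) by <- c(by, .own = own)
  structure(list(kind = "parameters", total = sum(by), millions = sum(by) / 1e6,
                 breakdown = data.frame(submodule = names(by), count = as.numeric(by),
                                        row.names = NULL)),
            class = "lmtb_arch_stats")
}

#' Count FLOPs of a detector at a given input size
#'
#' Propagates shapes analytically through the graph and accumulates
#' 2 x multiply-accumulates over all convolutional and linear operations
#' (including the attention projections and, for the baseline attention, the
#' token similarity matmuls). Pooling, resizing and activations are not
#' counted; normalisation is fused into the convolutions.
#'
#' @param g detector from [build_detector()].
#' @param input_hw input image side length (default 640).
#' @return an `lmtb_arch_stats` object with `total` FLOPs, `gflops`, and a
#'   per-stage breakdown.
#' @export
count_flops <- function(g, input_hw = 640L) {
  stopifnot(inherits(g, "lmtb_detector"))
  if (input_hw %% 32L != 0L)
    stop("input size must be a multiple of 32", call. = FALSE)
  tr <- mod_trace(g, c(input_hw, input_hw, 3L))
  fl <- 2 * tr$by
  structure(list(kind = "flops", input_hw = input_hw, total = 2 * tr$macs,
                 gflops = 2 * tr$macs / 1e9,
                 breakdown = data.frame(submodule = names(fl), count = as.numeric(fl),
                                        row.names = NULL)),
            class = "lmtb_arch_stats")
}

#' @export
print.lmtb_arch_stats <- function(x, ...) {
  if (x$kind == "parameters") {
    cat(sprintf("trainable parameters: %s (%.4f M)\n",
                format(x$total, big.mark = ","), x$millions))
  } else {
    cat(sprintf("FLOPs at %dx%d: %s (%.4f G)\n", x$input_hw, x$input_hw,
                format(x$total, big.mark = ","), x$gflops))
  }
  df <- x$breakdown
  df$count <- format(df$count, big.mark = ",")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Audit a detector variant
#'
#' Convenience wrapper building a variant and reporting parameters and FLOPs,
#' mirroring the ablation rows of the architecture study.
#'
#' @inheritParams build_detector
#' @param input_hw FLOP-count input size.
#' @return list with `params` and `flops` stats.
#' @export
audit_variant <- function(variant = "lmtb", input_hw = 640L, scale = "n",
                          nc = 1L, seed = 1L) {
  g <- build_detector(variant, scale = scale, nc = nc, seed = seed)
  list(variant = variant,
       params = count_parameters(g),
       flops = count_flops(g, input_hw))
}
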
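#' Save a trained model to a checkpoint file
#'
#' Serialises the architecture configuration, all learned tensors and the
#' internal target scaler into a single file.
#'
#' @param model A `dcan_model` or `rnn_model`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_model_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("dcan_model", "rnn_model")))
  saveRDS(list(class = class(model), config = model$config,
               params = model$params,
               target_scaler = model$target_scaler,
               n_parameters = model$n_parameters,
               package_version = as.character(utils::packageVersion("dcanet"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_model_checkpoint()].
#' @return The reconstructed model.
#' @export
load_model_checkpoint <- function(path) {
  obj <- readRDS(path)
  structure(list(config = obj$config, params = obj$params,
                 target_scaler = obj$target_scaler,
                 n_parameters = obj$n_parameters),
            class = obj$class)
}

#' Residual and Bland-Altman agreement plots
#'
#' Writes two PNG files: predicted-vs-actual residuals against the
#' observed score, and a Bland-Altman scatter (difference against mean)
#' with the bias and 95% limits of agreement.
#'
#' @param y,yhat Observed and predicted motor-UPDRS scores.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
agreement_plots <- function(y, yhat, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(dir, "residuals.png")
  ba_path <- file.path(dir, "bland_altman.png")
  grDevices::png(res_path, width = 720, height = 540)
  plot(y, yhat - y, pch = 20, col = "#00000055",
       xlab = "observed motor UPDRS", ylab = "residual (predicted - observed)",
       main = "Residuals")
  abline(h = 0, lty = 2)
  grDevices::dev.off()
  ba <- bland_altman(y, yhat)
  grDevices::png(ba_path, width = 720, height = 540)
  plot((y + yhat) / 2, yhat - y, pch = 20, col = "#00000055",
       xlab = "mean of observed and predicted",
       ylab = "difference (predicted - observed)",
       main = "Bland-Altman agreement")
  abline(h = c(ba$bias, ba$loa_lower, ba$loa_upper),
         lty = c(1, 2, 2), col = c("black", "red", "red"))
  grDevices::dev.off()
  invisible(c(res_path, ba_path))
}
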
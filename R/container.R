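# Tensor container: a hierarchical on-disk store of named dense tensors with
# shape and mode-name metadata, serialized losslessly (64-bit doubles) via
# native R serialization.  Also carries recursive-model states.

CONTAINER_VERSION <- 1L

#' Write named tensors to a container file
#'
#' @param path output file path.
#' @param tensors named list of numeric vectors/matrices/arrays.  Mode
#'   names may be attached to each tensor as a character
#'   \code{attr(x, "modes")} of length \code{tensor_order(x)}.
#' @return \code{path}, invisibly.
#' @export
write_tensor_container <- function(path, tensors) {
  if (!is.list(tensors) || is.null(names(tensors)) ||
      any(names(tensors) == ""))
    stop("'tensors' must be a fully named list", call. = FALSE)
  entries <- lapply(tensors, function(x) {
    check_tensor(x)
    list(shape = tensor_dim(x),
         modes = attr(x, "modes"),
         values = as.double(as.vector(x)))
  })
  saveRDS(list(format = "rnpls-tensor-container",
               version = CONTAINER_VERSION, entries = entries),
          path)
  invisible(path)
}

#' Read tensors from a container file
#'
#' @param path container file written by [write_tensor_container()].
#' @param names optional character vector of dataset names to extract; an
#'   informative error is raised if any is missing.
#' @return Named list of tensors with their mode-name metadata restored.
#' @export
read_tensor_container <- function(path, names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "rnpls-tensor-container"))
    stop("'", path, "' is not a tensor container", call. = FALSE)
  entries <- obj$entries
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(entries))
    if (length(missing) > 0L)
      stop("dataset(s) not found in container: ",
           paste(missing, collapse = ", "),
           " (available: ", paste(base::names(entries), collapse = ", "),
           ")", call. = FALSE)
    entries <- entries[names]
  }
  lapply(entries, function(e) {
    x <- if (length(e$shape) == 1L) e$values else array(e$values, e$shape)
    if (!is.null(e$modes)) attr(x, "modes") <- e$modes
    x
  })
}

#' Save a recursive NPLS state to a container file
#'
#' Serializes the loading tensors, per-factor projectors, latent
#' coefficients and scalars of an \code{"rnpls_state"} so a stream can be
#' resumed later with [rnpls_update()].
#'
#' @param state an \code{"rnpls_state"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
save_rnpls_state <- function(state, path) {
  stopifnot(inherits(state, "rnpls_state"))
  m <- state$model
  tensors <- list(
    L_X = state$L_X,
    L_Y = state$L_Y,
    C_latent = m$C_latent,
    scalars = c(nfactors = state$nfactors, lambda = state$lambda,
                n_seen = state$n_seen,
                resid_ratio = state$diagnostics$resid_ratio,
                n_x_modes = length(m$x_shape),
                n_y_modes = length(m$y_shape)),
    x_shape = as.double(m$x_shape),
    y_shape = if (length(m$y_shape) == 0L) 0 else as.double(m$y_shape),
    T_scores = m$T
  )
  for (f in seq_len(state$nfactors)) {
    for (k in seq_along(m$factors[[f]]$w))
      tensors[[sprintf("w_f%d_m%d", f, k)]] <- m$factors[[f]]$w[[k]]
    for (k in seq_along(m$factors[[f]]$q))
      tensors[[sprintf("q_f%d_m%d", f, k)]] <- m$factors[[f]]$q[[k]]
  }
  write_tensor_container(path, tensors)
}

#' Load a recursive NPLS state from a container file
#'
#' @param path file written by [save_rnpls_state()].
#' @return An \code{"rnpls_state"}.
#' @export
load_rnpls_state <- function(path) {
  tl <- read_tensor_container(path)
  sc <- tl$scalars
  names(sc) <- c("nfactors", "lambda", "n_seen", "resid_ratio",
                 "n_x_modes", "n_y_modes")
  nf <- as.integer(sc[["nfactors"]])
  x_shape <- as.integer(tl$x_shape)
  y_shape <- if (sc[["n_y_modes"]] == 0) integer(0)
             else as.integer(tl$y_shape)
  factors <- lapply(seq_len(nf), function(f) {
    w <- lapply(seq_along(x_shape), function(k)
      tl[[sprintf("w_f%d_m%d", f, k)]])
    q <- if (length(y_shape) == 0L) list()
         else lapply(seq_along(y_shape), function(k)
           tl[[sprintf("q_f%d_m%d", f, k)]])
    t_f <- tl$T_scores[, f]
    list(w = w, q = q, t = t_f, u = t_f)
  })
  model <- structure(list(
    factors = factors, T = tl$T_scores,
    C_latent = matrix(tl$C_latent, nrow = nf),
    x_shape = x_shape, y_shape = y_shape, nfactors = nf,
    residual_norms = c(X = NA_real_, Y = NA_real_)
  ), class = "npls_model")
  structure(list(
    nfactors = nf, lambda = sc[["lambda"]],
    L_X = tl$L_X, L_Y = tl$L_Y, model = model,
    n_seen = as.integer(sc[["n_seen"]]),
    diagnostics = list(resid_ratio = sc[["resid_ratio"]],
                       orth_error = NA_real_, x_resid_orth = NA_real_,
                       y_resid_orth = NA_real_)
  ), class = "rnpls_state")
}
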
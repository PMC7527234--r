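#' The published final scoring weights
#'
#' The five-element weight vector reported by the original study for
#' converting a five-class morphology probability vector into a transfer
#' score (classes 1 through 5).  Note the strictly increasing order across
#' classes: non-blastocyst classes carry large negative weights,
#' blastocyst classes positive ones.
#'
#' @return a named numeric vector of length 5.
#' @examples
#' transfer_score(published_weights(), c(0, 0, 0, 0, 1))
#' @export
published_weights <- function() {
  c(w1 = -10.01226347, w2 = -3.63697951, w3 = -3.32090987,
    w4 = 2.15367795, w5 = 2.8715555)
}

check_weights <- function(w) {
  w <- as.numeric(w)
  if (length(w) != 5L || any(!is.finite(w))) {
    stop("a weight vector must have 5 finite components", call. = FALSE)
  }
  w
}

#' Serialize a weight vector (with provenance) to a JSON document
#'
#' @param fit a \code{ga_fit} object from \code{\link{ga_evolve}}, or a bare
#'   5-element weight vector.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_weights <- function(fit, path) {
  if (inherits(fit, "ga_fit")) {
    doc <- list(weights = as.numeric(fit$weights),
                generations = fit$generations,
                converged = fit$converged,
                seed = if (is.null(fit$config$seed)) NULL else fit$config$seed,
                config = fit$config[setdiff(names(fit$config), "seed")])
  } else {
    doc <- list(weights = check_weights(fit))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a weight vector written by \code{\link{write_weights}}
#'
#' @param path file to read.
#' @return a numeric weight vector of length 5, with the remaining document
#'   fields attached as attributes.
#' @export
read_weights <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- check_weights(doc$weights)
  for (f in setdiff(names(doc), "weights")) attr(w, f) <- doc[[f]]
  w
}
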
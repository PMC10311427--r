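# Versioned JSON serialization of fits and cutoff tables, so a decision
# run can be reproduced without refitting.

SERIAL_FORMAT <- "digirop-fit-1"

#' Serialize a fitted object to JSON
#'
#' Writes a `digirop_prescreen`, `digirop_screen` or `rop_cutoff_table`
#' to a versioned JSON document that [read_digirop()] restores exactly.
#'
#' @param object the fitted object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_digirop <- function(object, path) {
  doc <- if (inherits(object, "digirop_prescreen")) {
    list(format = SERIAL_FORMAT, kind = "prescreen",
         basis = unclass(object$basis),
         coefficients = as.list(object$coefficients),
         vcov = object$vcov, fit_meta = object$fit_meta,
         n_events = object$n_events,
         ga_range = object$ga_range, bw_range = object$bw_range,
         version = object$version)
  } else if (inherits(object, "digirop_screen")) {
    list(format = SERIAL_FORMAT, kind = "screen",
         weeks = object$weeks,
         fits = lapply(object$fits, function(f)
           list(coefficients = as.list(f$coefficients), vcov = f$vcov,
                aic = f$aic, loglik = f$loglik, n = f$n,
                n_events = f$n_events, auc = f$auc,
                penalized = f$penalized)),
         version = object$version)
  } else if (inherits(object, "rop_cutoff_table")) {
    list(format = SERIAL_FORMAT, kind = "cutoffs",
         strata = rownames(object), stages = colnames(object),
         values = unclass(object), epsilon = attr(object, "epsilon"),
         version = attr(object, "version"))
  } else stopf("cannot serialize objects of class %s",
               paste(class(object), collapse = "/"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a fitted object from JSON
#'
#' @param path file written by [write_digirop()].
#' @return the restored object.
#' @export
read_digirop <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, SERIAL_FORMAT))
    stopf("%s is not a recognized fit document", path)
  if (doc$kind == "prescreen") {
    basis <- time_basis(doc$basis$type, doc$basis$knots, doc$basis$boundary)
    co <- unlist(doc$coefficients)
    vc <- if (!is.null(doc$vcov)) {
      m <- as.matrix(doc$vcov)
      dimnames(m) <- list(names(co), names(co))
      m
    }
    out <- new_prescreen_fit(basis, co, vcov = vc, meta = doc$fit_meta)
    out$n_events <- doc$n_events
    out$ga_range <- doc$ga_range
    out$bw_range <- doc$bw_range
    out
  } else if (doc$kind == "screen") {
    fits <- lapply(doc$fits, function(f) {
      co <- unlist(f$coefficients)
      vc <- as.matrix(f$vcov)
      dimnames(vc) <- list(names(co), names(co))
      list(coefficients = co, vcov = vc, aic = f$aic, loglik = f$loglik,
           n = f$n, n_events = f$n_events, auc = f$auc,
           penalized = f$penalized)
    })
    structure(list(weeks = doc$weeks, fits = fits, version = doc$version),
              class = "digirop_screen")
  } else if (doc$kind == "cutoffs") {
    m <- as.matrix(doc$values)
    dimnames(m) <- list(doc$strata, doc$stages)
    structure(m, epsilon = doc$epsilon, version = doc$version,
              class = c("rop_cutoff_table", "matrix"))
  } else stopf("unknown fit kind '%s'", doc$kind)
}
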
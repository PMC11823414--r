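## Parametrization container: JSON with full-precision doubles.
## Complex matrices are stored as paired re/im arrays; all floating point is
## serialized with 17 significant digits so a write -> read round trip is
## bit-faithful for IEEE doubles.

.cplx_to_list <- function(M) list(re = Re(M), im = Im(M))
.list_to_cplx <- function(x) {
  re <- do.call(rbind, lapply(x$re, unlist))
  im <- do.call(rbind, lapply(x$im, unlist))
  matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
}

#' Write an LVC parametrization container
#'
#' Serializes a reference parametrization to a hierarchical JSON container
#' holding energies, gradients, NAC vectors, the three SOC component
#' matrices (as re/im pairs), the anchor geometry with site flags, the spin
#' quantum number and the anchor time.  Floating-point payloads round-trip
#' bit-faithfully.
#'
#' @param param an [lvc_param()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_parametrization <- function(param, path) {
  stopifnot(inherits(param, "lvc_param"))
  obj <- list(
    format = "lvc-parametrization",
    version = 1L,
    anchor_time = param$anchor_time,
    spin_S = param$spin_S,
    n_states = n_states(param),
    n_sites = nrow(param$geometry),
    geometry = param$geometry,
    site_flags = param$site_flags,
    energies = param$energies,
    gradients = param$gradients,
    nacs = as.numeric(param$nacs),         # flattened column-major
    soc_x = .cplx_to_list(param$soc$x),
    soc_y = .cplx_to_list(param$soc$y),
    soc_z = .cplx_to_list(param$soc$z)
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

.need_field <- function(obj, field) {
  if (is.null(obj[[field]]))
    .stopf("parametrization container: missing field '%s'", field)
  obj[[field]]
}

#' Read and validate an LVC parametrization container
#'
#' Rejects malformed containers with a message naming the offending field.
#'
#' @param path file written by [write_parametrization()]
#' @return an [lvc_param()]
#' @export
read_parametrization <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fmt <- .need_field(obj, "format")
  if (!identical(fmt, "lvc-parametrization"))
    .stopf("parametrization container: field 'format' is '%s', expected 'lvc-parametrization'", fmt)
  n <- as.integer(.need_field(obj, "n_states"))
  ns <- as.integer(.need_field(obj, "n_sites"))
  ncart <- 3L * ns
  geom <- do.call(rbind, lapply(.need_field(obj, "geometry"), unlist))
  if (!identical(dim(geom), c(ns, 3L)))
    .stopf("parametrization container: field 'geometry' has shape %s, expected %d x 3",
           paste(dim(geom), collapse = " x "), ns)
  energies <- unlist(.need_field(obj, "energies"))
  if (length(energies) != n)
    .stopf("parametrization container: field 'energies' has length %d, expected %d",
           length(energies), n)
  grads <- do.call(rbind, lapply(.need_field(obj, "gradients"), unlist))
  if (!identical(dim(grads), c(n, ncart)))
    .stopf("parametrization container: field 'gradients' has shape %s, expected %d x %d",
           paste(dim(grads), collapse = " x "), n, ncart)
  nacs_flat <- unlist(.need_field(obj, "nacs"))
  if (length(nacs_flat) != n * n * ncart)
    .stopf("parametrization container: field 'nacs' has %d values, expected %d",
           length(nacs_flat), n * n * ncart)
  nacs <- array(nacs_flat, dim = c(n, n, ncart))
  soc <- list()
  for (a in c("x", "y", "z")) {
    key <- paste0("soc_", a)
    soc[[a]] <- tryCatch(.list_to_cplx(.need_field(obj, key)),
                         error = function(e)
                           .stopf("parametrization container: field '%s' malformed", key))
    if (!identical(dim(soc[[a]]), c(n, n)))
      .stopf("parametrization container: field '%s' has shape %s, expected %d x %d",
             key, paste(dim(soc[[a]]), collapse = " x "), n, n)
  }
  lvc_param(
    anchor_time = as.numeric(.need_field(obj, "anchor_time")),
    geometry = geom,
    site_flags = unlist(.need_field(obj, "site_flags")),
    energies = energies,
    gradients = grads,
    nacs = nacs,
    soc = soc,
    spin_S = as.numeric(.need_field(obj, "spin_S"))
  )
}
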
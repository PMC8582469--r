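# Parametric seed models: nested analytic solids read from reviewable
# per-seed data files (inst/extdata/seeds/), innermost component first.
# The local frame has the seed long axis along Z, origin at the centre of
# the active region, +Z towards the source tip.

SEED_IDS <- c("AmershamOncoseed6711", "BebigIsoseedI25S06", "NucletronMHDRv1",
              "VarianVS2000", "SpecM19", "NucletronMPDRv2")

.parse_seed_file <- function(path) {
  lines <- readLines(path)
  meta <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(ln)) stop("seed file missing field: ", key)
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  rows <- grep("^#|^[a-z_]+:|^\\s*$", lines, invert = TRUE, value = TRUE)
  tok <- strsplit(trimws(rows), "\\s+")
  comp <- data.frame(
    name = vapply(tok, `[[`, "", 1),
    kind = vapply(tok, `[[`, "", 2),
    r_mm = as.numeric(vapply(tok, `[[`, "", 3)),
    half_mm = as.numeric(vapply(tok, `[[`, "", 4)),
    r2_mm = as.numeric(vapply(tok, `[[`, "", 5)),
    z_mm = as.numeric(vapply(tok, `[[`, "", 6)),
    material = vapply(tok, `[[`, "", 7),
    role = vapply(tok, `[[`, "", 8),
    stringsAsFactors = FALSE)
  list(id = meta("id"), nuclide = meta("nuclide"),
       L_mm = as.numeric(meta("active_length_mm")),
       active_component = meta("active_component"),
       active_mode = meta("active_mode"),
       components = comp)
}

.seed_cpp_spec <- function(sd) {
  phys <- physics_library()
  solids <- lapply(seq_len(nrow(sd$components)), function(i) {
    row <- sd$components[i, ]
    list(kind = row$kind, r = row$r_mm, h = row$half_mm, r2 = row$r2_mm,
         tr = c(0, 0, row$z_mm), rot = NULL)
  })
  mat <- vapply(sd$components$material,
                function(m) .material_index(m) - 1L, integer(1))
  sp <- line_spectrum(sd$nuclide)
  list(solids = solids, mat = unname(mat),
       active = match(sd$active_component, sd$components$name) - 1L,
       active_mode = if (sd$active_mode == "surface") 1L else 0L,
       lineE = sp$energy, lineW = sp$weight, L = sd$L_mm)
}

#' Build one of the six commercial seed models
#'
#' Constructs the nested-solid model of a brachytherapy source from its data
#' file: component solids (innermost to outermost) with materials, the
#' radioactive region, the emission spectrum and the active length L.  The
#' local frame follows the usual source convention: origin at the centre of
#' the active region, +Z through the source tip; HDR/PDR models carry a
#' drive-cable stub on the -Z side which breaks tip/cable symmetry.
#'
#' @param seed_id one of AmershamOncoseed6711, BebigIsoseedI25S06,
#'   NucletronMHDRv1, VarianVS2000, SpecM19, NucletronMPDRv2
#' @return object of class `seed_model`
#' @examples
#' s <- build_seed("AmershamOncoseed6711")
#' s$nuclide
#' @export
build_seed <- function(seed_id) {
  if (!seed_id %in% SEED_IDS)
    stop("unknown seed id: ", seed_id, " (known: ",
         paste(SEED_IDS, collapse = ", "), ")")
  path <- system.file("extdata", "seeds", paste0(seed_id, ".txt"),
                      package = "brachymc")
  sd <- .parse_seed_file(path)
  sd$cpp <- .seed_cpp_spec(sd)
  class(sd) <- "seed_model"
  sd
}

#' @export
print.seed_model <- function(x, ...) {
  cat("<seed_model>", x$id, sprintf("(%s, L = %g mm, active: %s/%s)\n",
      x$nuclide, x$L_mm, x$active_component, x$active_mode))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Analytic volume of a seed component (mm^3)
#' @param seed a [build_seed()] model
#' @param component component name (default: the active region)
#' @export
component_volume <- function(seed, component = seed$active_component) {
  row <- seed$components[seed$components$name == component, ]
  if (!nrow(row)) stop("no component named ", component)
  switch(row$kind,
         cylinder = pi * row$r_mm^2 * 2 * row$half_mm,
         capsule = pi * row$r_mm^2 * 2 * row$half_mm + 4 / 3 * pi * row$r_mm^3,
         sphere = 4 / 3 * pi * row$r_mm^3,
         `cone-frustum` = pi * 2 * row$half_mm / 3 *
           (row$r_mm^2 + row$r_mm * row$r2_mm + row$r2_mm^2),
         stop("unknown solid kind"))
}

#' Sample primary emissions from the active region of a seed
#'
#' Positions are uniform over the active region (volume-uniform, or uniform
#' over the lateral surface for coated sources such as the 6711), directions
#' isotropic, energies drawn from the nuclide line spectrum; weight 1.
#'
#' @param seed a [build_seed()] model
#' @param n number of emissions
#' @param rng_seed RNG stream seed
#' @return list with `position` (n x 3, mm), `direction` (n x 3, unit),
#'   `energy_keV`, `weight`
#' @export
sample_emission <- function(seed, n, rng_seed = 1) {
  m <- cpp_sample_emission(seed$cpp, n, rng_seed)
  list(position = m[, 1:3, drop = FALSE], direction = m[, 4:6, drop = FALSE],
       energy_keV = m[, 7], weight = rep(1, nrow(m)))
}

#' Trace a ray through a seed model
#'
#' Returns the ordered material segments the ray crosses from its start
#' point to where it exits the outermost solid; innermost component wins
#' where solids are nested.
#'
#' @param seed a [build_seed()] model
#' @param origin start point, mm (seed frame)
#' @param direction unit vector
#' @return data.frame with `length_mm` and `material`
#' @export
trace_ray <- function(seed, origin, direction) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be a unit vector")
  m <- cpp_trace(seed$cpp, as.numeric(origin), as.numeric(direction))
  if (!nrow(m)) return(data.frame(length_mm = numeric(0),
                                  material = character(0)))
  mats <- names(physics_library()$materials)
  data.frame(length_mm = m[, 1],
             material = ifelse(m[, 2] < 0, "vacuum", mats[m[, 2] + 1]),
             stringsAsFactors = FALSE)
}

#' Rigid pose (rotation + translation)
#'
#' @param translation xyz offset in mm
#' @param axis rotation axis (need not be normalized)
#' @param angle_deg rotation angle about `axis`, degrees
#' @return object of class `pose` with fields `R` (3x3) and `t`
#' @export
pose <- function(translation = c(0, 0, 0), axis = c(0, 0, 1), angle_deg = 0) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  stopifnot(abs(det(R) - 1) < 1e-9)
  structure(list(R = R, t = as.numeric(translation)), class = "pose")
}

#' Apply a pose to points and directions
#' @param p a [pose()]
#' @param points n x 3 matrix of positions (mm); may be NULL
#' @param directions n x 3 matrix of directions; may be NULL
#' @return list with transformed `points` and `directions`
#' @export
apply_pose <- function(p, points = NULL, directions = NULL) {
  out <- list()
  if (!is.null(points))
    out$points <- sweep(points %*% t(p$R), 2, p$t, "+")
  if (!is.null(directions))
    out$directions <- directions %*% t(p$R)
  out
}
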
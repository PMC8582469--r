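# Embedded photon-interaction data: elements, materials, radionuclide spectra.
# Element tables live in inst/extdata/xs/ as delimited text (one file per
# element, provenance in the file headers) and are loaded once per session.

.brachy <- new.env(parent = emptyenv())

.parse_element_file <- function(path) {
  lines <- readLines(path)
  getmeta <- function(key, default = NA_real_) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    if (!length(ln)) return(default)
    sub(paste0("^# ", key, ":\\s*"), "", ln[1])
  }
  num <- function(key, default = NA_real_) {
    v <- getmeta(key, NA)
    if (is.na(v)) default else as.numeric(v)
  }
  nums <- function(key) {
    v <- getmeta(key, NA)
    if (is.na(v)) numeric(0) else as.numeric(strsplit(trimws(v), "\\s+")[[1]])
  }
  ixs <- grep("^@xs", lines)
  iff <- grep("^@ff", lines)
  isf <- grep("^@sf", lines)
  nxs <- as.integer(sub("@xs\\s+", "", lines[ixs]))
  nff <- as.integer(sub("@ff\\s+", "", lines[iff]))
  nsf <- as.integer(sub("@sf\\s+", "", lines[isf]))
  xs <- do.call(rbind, lapply(strsplit(lines[(ixs + 1):(ixs + nxs)], "\\s+"),
                              as.numeric))
  ff <- do.call(rbind, lapply(strsplit(lines[(iff + 1):(iff + nff)], "\\s+"),
                              as.numeric))
  sf <- do.call(rbind, lapply(strsplit(lines[(isf + 1):(isf + nsf)], "\\s+"),
                              as.numeric))
  kjump <- num("kjump", 0)
  list(
    name = sub("\\.txt$", "", basename(path)),
    Z = num("Z"), A = num("A"),
    E = xs[, 1], photo = xs[, 2], incoh = xs[, 3], coh = xs[, 4],
    muen = xs[, 5],
    kedge = num("kedge_keV", -1),
    kfrac = if (kjump > 0) 1 - 1 / kjump else 0,
    kyield = num("kyield", 0),
    klineE = nums("klines_keV"), klineW = nums("klines_w"),
    ffx = ff[, 1], ffF = ff[, 2], ffS = sf[, 2])
}

.parse_materials_file <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  mats <- list()
  cur <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "material") {
      if (!is.null(cur)) mats[[cur$name]] <- cur
      cur <- list(name = tok[2], density = as.numeric(tok[3]),
                  elements = character(0), wfrac = numeric(0))
    } else {
      cur$elements <- c(cur$elements, tok[1])
      cur$wfrac <- c(cur$wfrac, as.numeric(tok[2]))
    }
  }
  if (!is.null(cur)) mats[[cur$name]] <- cur
  mats
}

.parse_spectra_file <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "nuclide") {
      cur <- tok[2]
      out[[cur]] <- list(energy = numeric(0), prob = numeric(0))
    } else {
      out[[cur]]$energy <- c(out[[cur]]$energy, as.numeric(tok[1]))
      out[[cur]]$prob <- c(out[[cur]]$prob, as.numeric(tok[2]))
    }
  }
  out
}

# Load (and cache) the full physics library in the layout the C++ core expects.
physics_library <- function() {
  if (!is.null(.brachy$phys)) return(.brachy$phys)
  dir <- system.file("extdata", "xs", package = "brachymc")
  files <- list.files(dir, pattern = "^[A-Z][a-z]?\\.txt$", full.names = TRUE)
  elements <- lapply(files, .parse_element_file)
  names(elements) <- vapply(elements, `[[`, "", "name")
  mats <- .parse_materials_file(file.path(dir, "materials.txt"))
  materials <- lapply(mats, function(m) {
    idx <- match(m$elements, names(elements))
    if (anyNA(idx)) stop("material ", m$name, " uses unknown element")
    list(name = m$name, density = m$density, elem = idx, wfrac = m$wfrac)
  })
  .brachy$phys <- list(elements = elements, materials = materials,
                       spectra = .parse_spectra_file(file.path(dir, "spectra.txt")))
  .brachy$phys
}

.material_index <- function(name) {
  phys <- physics_library()
  i <- match(name, names(phys$materials))
  if (is.na(i)) stop("unknown material: ", name)
  i
}

#' Materials known to the physics library
#' @return character vector of material names
#' @export
list_materials <- function() names(physics_library()$materials)

#' Define or look up a material
#'
#' A material is a mass density plus element mass fractions.  With only a
#' name, the shipped library entry (ICRP/ICRU tissues, water, air, seed
#' construction alloys) is returned; a custom material can be built by giving
#' `density` and a named `composition` vector of mass fractions.
#'
#' @param name material name
#' @param density mass density in g/cm3 (custom materials)
#' @param composition named numeric vector of element mass fractions summing
#'   to 1 (custom materials)
#' @return an object of class `brachy_material`
#' @export
material <- function(name, density = NULL, composition = NULL) {
  phys <- physics_library()
  if (is.null(composition)) {
    m <- phys$materials[[name]]
    if (is.null(m)) stop("unknown material: ", name)
    comp <- stats::setNames(m$wfrac, names(phys$elements)[m$elem])
    density <- m$density
  } else {
    if (is.null(density) || density <= 0) stop("density must be > 0")
    if (abs(sum(composition) - 1) > 1e-9)
      stop("mass fractions must sum to 1")
    unknown <- setdiff(names(composition), names(phys$elements))
    if (length(unknown)) stop("unknown element: ", paste(unknown, collapse = ", "))
    comp <- composition
  }
  structure(list(name = name, density = density, composition = comp),
            class = "brachy_material")
}

#' @export
print.brachy_material <- function(x, ...) {
  cat("<material>", x$name, sprintf("(%.4g g/cm3)\n", x$density))
  print(round(x$composition, 5))
  invisible(x)
}

.as_material <- function(material) {
  if (inherits(material, "brachy_material")) material
  else material(material)
}

.elem_channel <- function(el, channel) {
  switch(channel,
         photoelectric = el$photo,
         compton = el$incoh,
         rayleigh = el$coh,
         energy_absorption = el$muen,
         total = el$photo + el$incoh + el$coh,
         stop("unknown channel: ", channel))
}

#' Mass attenuation / energy-absorption coefficient of a material
#'
#' Applies the elemental mixture rule `sum_i w_i (mu/rho)_i(E)` with log-log
#' interpolation on the shipped element tables.
#'
#' @param material a material name or [material()] object
#' @param energy_keV photon energies, keV (within the 1--1000 keV table span)
#' @param channel one of `"total"`, `"photoelectric"`, `"compton"`,
#'   `"rayleigh"`, `"energy_absorption"`
#' @return coefficients in cm2/g, same length as `energy_keV`
#' @export
mu_over_rho <- function(material, energy_keV, channel = "total") {
  phys <- physics_library()
  mat <- .as_material(material)
  channel <- match.arg(channel, c("total", "photoelectric", "compton",
                                  "rayleigh", "energy_absorption"))
  out <- numeric(length(energy_keV))
  for (el_name in names(mat$composition)) {
    el <- phys$elements[[el_name]]
    if (any(energy_keV < min(el$E) | energy_keV > max(el$E)))
      stop("energy outside table span [", min(el$E), ", ", max(el$E), "] keV")
    y <- .elem_channel(el, channel)
    out <- out + mat$composition[[el_name]] *
      exp(stats::approx(log(el$E), log(pmax(y, 1e-300)), log(energy_keV))$y)
  }
  unname(out)
}

# phys list with one extra (possibly custom) material appended; returns the
# 0-based C++ index of that material
.phys_with_material <- function(mat) {
  phys <- physics_library()
  mat <- .as_material(mat)
  i <- match(mat$name, names(phys$materials))
  if (!is.na(i) && is.null(attr(mat, "custom"))) {
    lib <- phys$materials[[i]]
    same <- isTRUE(all.equal(lib$density, mat$density)) &&
      length(lib$elem) == length(mat$composition)
    if (same) return(list(phys = phys, idx = i - 1L))
  }
  idx <- match(names(mat$composition), names(phys$elements))
  phys$materials <- c(phys$materials, list(
    list(name = mat$name, density = mat$density, elem = idx,
         wfrac = unname(mat$composition))))
  list(phys = phys, idx = length(phys$materials) - 1L)
}

#' Sample the interaction channel at a given energy
#'
#' Draws photoelectric / Compton / Rayleigh with probabilities proportional
#' to the partial mass attenuation coefficients at `energy_keV`.
#'
#' @inheritParams mu_over_rho
#' @param n number of draws
#' @param rng_seed integer seed for the transport RNG stream
#' @return factor vector with levels photoelectric, compton, rayleigh
#' @export
sample_channel <- function(material, energy_keV, n, rng_seed = 1) {
  pw <- .phys_with_material(material)
  ch <- cpp_sample_channel(pw$phys, pw$idx, energy_keV, n, rng_seed)
  factor(c("photoelectric", "compton", "rayleigh")[ch],
         levels = c("photoelectric", "compton", "rayleigh"))
}

#' Radionuclide line spectrum
#'
#' @param nuclide `"I125"` or `"Ir192"`
#' @return object of class `line_spectrum` with per-decay emission
#'   probabilities and normalized sampling weights
#' @export
line_spectrum <- function(nuclide) {
  sp <- physics_library()$spectra[[nuclide]]
  if (is.null(sp)) stop("unknown nuclide: ", nuclide)
  structure(list(nuclide = nuclide, energy = sp$energy, prob = sp$prob,
                 weight = sp$prob / sum(sp$prob)),
            class = "line_spectrum")
}

#' Sample photon line energies from a spectrum
#'
#' Uses R's RNG stream (seed with [set.seed()] for reproducibility).
#'
#' @param spectrum a [line_spectrum()]
#' @param n number of draws
#' @return energies in keV
#' @export
sample_line <- function(spectrum, n) {
  if (!length(spectrum$energy)) stop("empty spectrum")
  if (length(spectrum$energy) == 1L) return(rep(spectrum$energy, n))
  sample(spectrum$energy, n, replace = TRUE, prob = spectrum$weight)
}
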
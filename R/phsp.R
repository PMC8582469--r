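# Phase-space files: generation by transporting decay photons out of the
# seed (vacuum outside; capsule attenuation, scatter and source fluorescence
# shape the record), a documented fixed-width binary format, and
# pose-transformed replay as a source.
#
# .phsp binary layout (little endian):
#   bytes 0..7    magic "BPHSP001" (8 ASCII bytes; last 3 = format version)
#   bytes 8..11   int32 header length H
#   bytes 12..11+H ASCII header "key=value" lines: seed_id, nuclide,
#                 n_primary, n_records, rng_seed, checksum
#   body          n_records fixed-width 33-byte records:
#                 uint8 particle type (1 = photon), then float32
#                 E_keV, x, y, z (mm, seed local frame), ux, uy, uz, weight

PHSP_MAGIC <- "BPHSP001"
.PHSP_RECBYTES <- 33L

.phsp_checksum <- function(raw_body) {
  # byte sum folded with the length; exact in doubles far beyond any
  # realistic file size
  s <- sum(as.double(as.integer(raw_body)))
  n <- length(raw_body)
  (s * 4099 + n) %% 2^49
}

.phsp_body_raw <- function(records) {
  n <- nrow(records)
  fraw <- writeBin(as.numeric(t(records)), raw(), size = 4, endian = "little")
  as.vector(rbind(matrix(as.raw(1L), 1, n),
                  matrix(fraw, 32, n)))
}

#' Generate a phase-space file for a seed
#'
#' Samples decays in the active region, transports each photon through the
#' seed's own materials (vacuum outside) and records every photon crossing
#' the outer capsule surface outward, until `n_records` are stored.  All
#' gammas crossing the capture surface are recorded -- scattered primaries
#' and K fluorescence born in the source alike -- while electrons are never
#' tracked (photon-only file).  Records are in the seed local frame so one
#' file serves every pose.
#'
#' @param seed a [build_seed()] model
#' @param n_records number of records to store
#' @param rng_seed generation RNG seed (stored in the header)
#' @param max_factor abort if more than `max_factor * n_records` primaries
#'   fail to yield the requested records (generation stall)
#' @param fluorescence record K fluorescence photons escaping the source
#'   (they are gammas crossing the capture surface and a substantial part of
#'   the emission of silver-rod seeds); set FALSE for a primary-line-only
#'   file
#' @return object of class `phsp`
#' @export
generate_phsp <- function(seed, n_records, rng_seed = 1, max_factor = 50,
                          fluorescence = TRUE) {
  stopifnot(n_records >= 1)
  res <- cpp_generate_phsp(physics_library(), seed$cpp, n_records, rng_seed,
                           max_factor, fluorescence)
  rec <- res$records
  colnames(rec) <- c("E_keV", "x", "y", "z", "ux", "uy", "uz", "weight")
  structure(list(
    header = list(version = PHSP_MAGIC, seed_id = seed$id,
                  nuclide = seed$nuclide, n_primary = res$n_primary,
                  n_records = nrow(rec), rng_seed = rng_seed),
    records = rec), class = "phsp")
}

#' @export
print.phsp <- function(x, ...) {
  h <- x$header
  cat(sprintf("<phsp> %s (%s): %d records from %g primaries (escape fraction %.3f)\n",
              h$seed_id, h$nuclide, h$n_records, h$n_primary,
              h$n_records / h$n_primary))
  cat(sprintf("  mean E = %.2f keV\n", mean(x$records[, "E_keV"])))
  invisible(x)
}

#' Write a phase-space object to a .phsp binary file
#' @param phsp a `phsp` object
#' @param path output file
#' @export
write_phsp <- function(phsp, path) {
  body <- .phsp_body_raw(phsp$records)
  h <- phsp$header
  hdr <- paste0("seed_id=", h$seed_id, "\nnuclide=", h$nuclide,
                "\nn_primary=", format(h$n_primary, scientific = FALSE),
                "\nn_records=", h$n_records,
                "\nrng_seed=", format(h$rng_seed, scientific = FALSE),
                "\nchecksum=", format(.phsp_checksum(body), scientific = FALSE),
                "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(PHSP_MAGIC), con)
  writeBin(as.integer(nchar(hdr)), con, size = 4, endian = "little")
  writeBin(charToRaw(hdr), con)
  writeBin(body, con)
  invisible(path)
}

.phsp_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phsp_error", "error", "condition")))
}

#' Read a .phsp binary file
#'
#' Validates magic/version, header consistency and the body checksum;
#' truncated bodies, checksum mismatches and unknown versions raise distinct
#' error classes (`phsp_truncated`, `phsp_checksum`, `phsp_version`).
#'
#' @param path file written by [write_phsp()]
#' @return a `phsp` object
#' @export
read_phsp <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, PHSP_MAGIC))
    .phsp_error(paste0("unknown phase-space format/version: ", magic),
                "phsp_version")
  hl <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- rawToChar(readBin(con, "raw", hl))
  kv <- strsplit(strsplit(hdr, "\n")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
  n_rec <- as.numeric(vals[["n_records"]])
  body_expected <- n_rec * .PHSP_RECBYTES
  body <- readBin(con, "raw", sz)              # read what is there
  if (length(body) < body_expected)
    .phsp_error(sprintf("truncated body: %d bytes, expected %d",
                        length(body), body_expected), "phsp_truncated")
  body <- body[seq_len(body_expected)]
  if (abs(.phsp_checksum(body) - as.numeric(vals[["checksum"]])) > 0.5)
    .phsp_error("checksum mismatch", "phsp_checksum")
  rec <- matrix(NA_real_, n_rec, 8,
                dimnames = list(NULL, c("E_keV", "x", "y", "z",
                                        "ux", "uy", "uz", "weight")))
  bm <- matrix(body, nrow = .PHSP_RECBYTES)
  types <- as.integer(bm[1, ])
  if (any(types != 1L)) .phsp_error("unknown particle type code", "phsp_version")
  floats <- readBin(as.raw(bm[-1, ]), "numeric", n_rec * 8, size = 4,
                    endian = "little")
  rec[] <- matrix(floats, ncol = 8, byrow = TRUE)
  structure(list(
    header = list(version = magic, seed_id = vals[["seed_id"]],
                  nuclide = vals[["nuclide"]],
                  n_primary = as.numeric(vals[["n_primary"]]),
                  n_records = n_rec,
                  rng_seed = as.numeric(vals[["rng_seed"]])),
    records = rec), class = "phsp")
}

#' Replay phase-space records as a world-frame particle stream
#'
#' Draws records uniformly with replacement (or cyclically in order), applies
#' the pose rotation to positions and directions and the pose translation to
#' positions; energies and weights are unchanged.  Uses R's RNG stream.
#'
#' @param phsp a `phsp` object
#' @param pose a [pose()]
#' @param n number of particles
#' @param cyclic draw records in stored order instead of resampling
#' @return list with `energy_keV`, `position`, `direction`, `weight`
#' @export
replay_source <- function(phsp, pose = brachymc::pose(), n = nrow(phsp$records),
                          cyclic = FALSE) {
  nr <- nrow(phsp$records)
  if (!nr) stop("empty phase-space file")
  idx <- if (cyclic) rep_len(seq_len(nr), n)
         else sample.int(nr, n, replace = TRUE)
  r <- phsp$records[idx, , drop = FALSE]
  tp <- apply_pose(pose, points = r[, c("x", "y", "z"), drop = FALSE],
                   directions = r[, c("ux", "uy", "uz"), drop = FALSE])
  list(energy_keV = unname(r[, "E_keV"]), position = unname(tp$points),
       direction = unname(tp$directions), weight = unname(r[, "weight"]))
}
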
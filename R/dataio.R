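## Bundle layout (BIDS-iEEG-inspired naming, not claiming compliance):
##   <root>/clinical.tsv, ground_truth.json, cohort.json
##   <root>/<hemi>/signals.tsv   (columns lfp1..lfp8, emg; uV)
##   <root>/<hemi>/events.tsv       (cue_time, emg_onset, emg_offset, artifact; s)
##   <root>/<hemi>/electrodes.tsv   (name, x, y, z, is_ring, inside_stn, subregion; mm)
##   <root>/<hemi>/recording.json   (hemisphere_id, fs, side)

validate_events <- function(ev, where = "events") {
  need <- c("cue_time", "emg_onset", "emg_offset", "artifact")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stopf("%s: missing column(s) %s", where, paste(miss, collapse = ", "))
  for (i in seq_len(nrow(ev))) {
    if (!(ev$cue_time[i] < ev$emg_onset[i] && ev$emg_onset[i] < ev$emg_offset[i]))
      stopf("%s row %d: requires cue < onset < offset (got %.3f, %.3f, %.3f)",
            where, i, ev$cue_time[i], ev$emg_onset[i], ev$emg_offset[i])
  }
  if (is.unsorted(ev$cue_time))
    stopf("%s: trials must be time-sorted", where)
  if (nrow(ev) > 1 && any(ev$emg_offset[-nrow(ev)] > ev$cue_time[-1]))
    stopf("%s: trials overlap", where)
  invisible(ev)
}

validate_contacts <- function(ct, where = "electrodes") {
  need <- c("contact_id", "x", "y", "z", "inside_stn", "subregion")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stopf("%s: missing column(s) %s", where, paste(miss, collapse = ", "))
  if (nrow(ct) != 8) stopf("%s: expected exactly 8 contacts, got %d", where, nrow(ct))
  if (!all(is.finite(as.matrix(ct[, c("x", "y", "z")]))))
    stopf("%s: non-finite coordinates", where)
  if (any(ct$inside_stn & ct$subregion == "outside"))
    stopf("%s: inside_stn contact labelled subregion 'outside'", where)
  invisible(ct)
}

#' Write one hemisphere recording bundle
#'
#' @param rec a `lead_recording`.
#' @param dir target directory (created).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- data.table::as.data.table(cbind(t(rec$lfp), rec$emg))
  data.table::setnames(sig, c(paste0("lfp", 1:8), "emg"))
  data.table::fwrite(sig, file.path(dir, "signals.tsv"), sep = "\t")
  data.table::fwrite(rec$events, file.path(dir, "events.tsv"), sep = "\t")
  el <- rec$contacts
  el$name <- sprintf("E%d", el$contact_id)
  data.table::fwrite(el[, c("name", "contact_id", "x", "y", "z", "is_ring",
                            "inside_stn", "subregion")],
                     file.path(dir, "electrodes.tsv"), sep = "\t")
  jsonlite::write_json(list(hemisphere_id = rec$hemisphere_id, fs = rec$fs,
                            side = rec$side),
                       file.path(dir, "recording.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read one hemisphere recording bundle
#'
#' Validates the event and electrode tables against their invariants
#' (cue < onset < offset, non-overlapping sorted trials, exactly 8
#' finite-coordinate contacts) and reports the offending row on failure.
#'
#' @param dir bundle directory.
#' @return a `lead_recording`.
#' @export
read_bundle <- function(dir) {
  need <- c("signals.tsv", "events.tsv", "electrodes.tsv", "recording.json")
  for (f in need) if (!file.exists(file.path(dir, f)))
    stopf("read_bundle: missing file %s in %s", f, dir)
  meta <- jsonlite::read_json(file.path(dir, "recording.json"), simplifyVector = TRUE)
  if (!is.numeric(meta$fs) || meta$fs <= 0) stopf("read_bundle: invalid fs")
  sig <- as.data.frame(data.table::fread(file.path(dir, "signals.tsv"), sep = "\t"))
  if (ncol(sig) != 9) stopf("read_bundle: expected 9 signal channels, got %d", ncol(sig))
  ev <- as.data.frame(data.table::fread(file.path(dir, "events.tsv"), sep = "\t"))
  validate_events(ev, file.path(dir, "events.tsv"))
  el <- as.data.frame(data.table::fread(file.path(dir, "electrodes.tsv"), sep = "\t"))
  validate_contacts(el, file.path(dir, "electrodes.tsv"))
  el <- el[order(el$contact_id), ]
  structure(list(hemisphere_id = meta$hemisphere_id, fs = meta$fs,
                 lfp = t(as.matrix(sig[, 1:8])),
                 emg = sig[[9]], events = ev,
                 contacts = el[, c("contact_id", "x", "y", "z", "is_ring",
                                   "inside_stn", "subregion")],
                 side = meta$side %||% "right"),
            class = "lead_recording")
}

#' Write a whole cohort bundle
#'
#' @param cohort a `synth_cohort`.
#' @param root cohort root directory.
#' @return `root`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$recordings))
    write_bundle(cohort$recordings[[id]], file.path(root, id))
  data.table::fwrite(cohort$clinical, file.path(root, "clinical.tsv"), sep = "\t")
  jsonlite::write_json(cohort$truth, file.path(root, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(hemispheres = names(cohort$recordings),
                            n_hemispheres = length(cohort$recordings),
                            seed = cohort$config$rng_seed),
                       file.path(root, "cohort.json"), auto_unbox = TRUE)
  invisible(root)
}

#' Read a cohort bundle
#'
#' @param root cohort root directory.
#' @return list with `recordings`, `clinical` (if present), `truth`
#'   (if present), `manifest`.
#' @export
read_cohort_bundle <- function(root) {
  manifest <- jsonlite::read_json(file.path(root, "cohort.json"), simplifyVector = TRUE)
  recs <- lapply(manifest$hemispheres, function(id) read_bundle(file.path(root, id)))
  names(recs) <- manifest$hemispheres
  clin <- NULL
  if (file.exists(file.path(root, "clinical.tsv")))
    clin <- as.data.frame(data.table::fread(file.path(root, "clinical.tsv"), sep = "\t"))
  truth <- NULL
  if (file.exists(file.path(root, "ground_truth.json")))
    truth <- jsonlite::read_json(file.path(root, "ground_truth.json"),
                                 simplifyVector = TRUE)
  list(recordings = recs, clinical = clin, truth = truth, manifest = manifest)
}

#' Mirror left-hemisphere coordinates onto the right
#'
#' Rigid mirror: negate x. An optional user-supplied 4x4 affine overrides
#' the mirror (applied to homogeneous coordinates) for users with their
#' own nonrigid-flip approximation.
#'
#' @param contacts contact data.frame with x, y, z.
#' @param side "left" or "right"; right is returned unchanged.
#' @param affine optional 4x4 matrix.
#' @return contact data.frame in right-hemisphere coordinates.
#' @export
flip_to_right <- function(contacts, side = "left", affine = NULL) {
  if (identical(side, "right")) return(contacts)
  xyz <- as.matrix(contacts[, c("x", "y", "z")])
  if (is.null(affine)) {
    xyz[, 1] <- -xyz[, 1]
  } else {
    stopifnot(all(dim(affine) == c(4, 4)))
    xyz <- t(affine %*% rbind(t(xyz), 1))[, 1:3]
  }
  contacts[, c("x", "y", "z")] <- xyz
  contacts
}

## Stable md5 of an R object via its canonical JSON serialization.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Write result tables with a metadata sidecar
#'
#' Every table is written as TSV with stable column order; a JSON sidecar
#' records the configuration hash, seed and package version.
#'
#' @param tables named list of data.frames.
#' @param path output directory.
#' @param config configuration object (hashed into the sidecar).
#' @param seed seed recorded in the sidecar.
#' @return paths of files written, invisibly.
#' @export
write_results <- function(tables, path, config = list(), seed = NA) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  stopifnot(is.list(tables), !is.null(names(tables)))
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".tsv"))
    data.table::fwrite(tables[[nm]], f, sep = "\t")
    files <- c(files, f)
  }
  meta <- list(config_hash = config_hash(config), seed = seed,
               version = as.character(utils::packageVersion("stnprop")),
               tables = names(tables))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(path, "metadata.json")))
}

#' Read a results directory written by [write_results()]
#'
#' @param path results directory.
#' @return named list of data.frames plus `metadata`.
#' @export
read_results <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"), simplifyVector = TRUE)
  out <- lapply(meta$tables, function(nm)
    as.data.frame(data.table::fread(file.path(path, paste0(nm, ".tsv")), sep = "\t")))
  names(out) <- meta$tables
  out$metadata <- meta
  out
}

#' Read/write an ellipsoid STN model as JSON
#'
#' @param model an ellipsoid `stn_model`.
#' @param path JSON file path.
#' @return For write, the path invisibly; for read, an `stn_model`.
#' @export
write_stn_model <- function(model, path) {
  stopifnot(model$kind == "ellipsoid")
  jsonlite::write_json(list(kind = "ellipsoid", center = model$center,
                            semi_axes = model$semi_axes,
                            rotation = as.numeric(model$rotation),
                            partition_frac = model$partition_frac),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stn_model
#' @export
read_stn_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stn_ellipsoid(center = j$center, semi_axes = j$semi_axes,
                rotation = matrix(j$rotation, 3, 3),
                partition_frac = j$partition_frac)
}
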
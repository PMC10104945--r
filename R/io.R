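# Study container I/O: a directory of CSV/JSON files with a fixed tree
#
#   <dir>/timing.json                 frame times (ms), R-wave markers (ms)
#   <dir>/views/{a4c,a2c,aplax}/geometry.json
#   <dir>/views/{a4c,a2c,aplax}/velocity.csv   frames x (beam*depth)
#   <dir>/traces/{a4c,a2c,aplax}.csv           trace points (x_mm, y_mm)
#   <dir>/traces/{a4c,a2c,aplax}.json          apex index, reference frame
#   <dir>/truth/...                   phantom ground truth (optional)
#
# Velocity matrices are stored depth-fastest (column b<j>_d<k>).

.viewDirs <- c("a4c", "a2c", "aplax")

#' Write a study container
#'
#' Serialises an [LVStudy-class] into the directory layout above. Writing
#' is deterministic: the same study writes byte-identical files.
#'
#' @param study an [LVStudy-class].
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "LVStudy"))
  validObject(study)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(frame_times_ms = frameTimes(study),
         r_wave_times_ms = rWaveTimes(study)),
    file.path(dir, "timing.json"), digits = NA)
  for (nm in .viewDirs) {
    v <- study@views[[nm]]
    vd <- file.path(dir, "views", nm)
    dir.create(vd, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(view_id = v@viewId,
           beam_angles_deg = v@beamAngles,
           depths_mm = v@depths,
           avc_override_ms = v@avcOverride),
      file.path(vd, "geometry.json"), digits = NA, null = "null")
    d <- dim(v@velocity)
    m <- matrix(aperm(v@velocity, c(3L, 2L, 1L)), nrow = d[1], byrow = TRUE)
    colnames(m) <- paste0("b", rep(seq_len(d[2]), each = d[3]),
                          "_d", rep(seq_len(d[3]), times = d[2]))
    data.table::fwrite(data.table::as.data.table(m),
                       file.path(vd, "velocity.csv"))
    tr <- study@traces[[nm]]
    dir.create(file.path(dir, "traces"), showWarnings = FALSE)
    data.table::fwrite(
      data.table::data.table(x_mm = tr@points[, 1], y_mm = tr@points[, 2]),
      file.path(dir, "traces", paste0(nm, ".csv")))
    jsonlite::write_json(
      list(view_id = tr@viewId, apex_index = tr@apexIndex,
           reference_frame = tr@referenceFrame),
      file.path(dir, "traces", paste0(nm, ".json")), digits = NA,
      auto_unbox = TRUE)
  }
  if (!is.null(study@truth)) {
    td <- file.path(dir, "truth")
    dir.create(td, showWarnings = FALSE)
    tru <- study@truth
    data.table::fwrite(data.table::as.data.table(tru@kinematics),
                       file.path(td, "kinematics.csv"))
    jsonlite::write_json(
      list(true_avc_ms = tru@trueAvcMs,
           reference_cycle_start_ms = tru@referenceCycleStartMs),
      file.path(td, "meta.json"), digits = NA, auto_unbox = TRUE)
    st <- data.table::as.data.table(tru@strain)
    data.table::setnames(st, paste0("seg_", 1:16))
    st <- cbind(data.table::data.table(time_ms = tru@frameTimes), st)
    data.table::fwrite(st, file.path(td, "strain.csv"))
    data.table::fwrite(
      data.table::data.table(time_ms = tru@frameTimes,
                             volume_mm3 = tru@volume),
      file.path(td, "volume.csv"))
  }
  invisible(dir)
}

#' Validate a study container directory
#'
#' Checks the container tree and schema; stops at the first failing path,
#' naming it.
#'
#' @param dir container directory.
#' @return TRUE, invisibly, when the container is valid.
#' @export
validateStudyDir <- function(dir) {
  need <- function(path) {
    if (!file.exists(file.path(dir, path)))
      stop(sprintf("invalid study container: missing %s", path))
  }
  need("timing.json")
  for (nm in .viewDirs) {
    need(file.path("views", nm, "geometry.json"))
    need(file.path("views", nm, "velocity.csv"))
    need(file.path("traces", paste0(nm, ".csv")))
    need(file.path("traces", paste0(nm, ".json")))
  }
  timing <- jsonlite::read_json(file.path(dir, "timing.json"),
                                simplifyVector = TRUE)
  for (f in c("frame_times_ms", "r_wave_times_ms")) {
    if (is.null(timing[[f]]))
      stop(sprintf("invalid study container: timing.json lacks %s", f))
  }
  for (nm in .viewDirs) {
    g <- jsonlite::read_json(file.path(dir, "views", nm, "geometry.json"),
                             simplifyVector = TRUE)
    for (f in c("view_id", "beam_angles_deg", "depths_mm")) {
      if (is.null(g[[f]]))
        stop(sprintf("invalid study container: views/%s/geometry.json lacks %s",
                     nm, f))
    }
  }
  invisible(TRUE)
}

#' Read a study container
#'
#' @param dir container directory written by [writeStudy()] (validated
#'   first).
#' @return an [LVStudy-class].
#' @export
readStudy <- function(dir) {
  validateStudyDir(dir)
  timing <- jsonlite::read_json(file.path(dir, "timing.json"),
                                simplifyVector = TRUE)
  views <- list()
  traces <- list()
  for (nm in .viewDirs) {
    vd <- file.path(dir, "views", nm)
    g <- jsonlite::read_json(file.path(vd, "geometry.json"),
                             simplifyVector = TRUE)
    m <- as.matrix(data.table::fread(file.path(vd, "velocity.csv")))
    nb <- length(g$beam_angles_deg)
    nd <- length(g$depths_mm)
    nf <- length(timing$frame_times_ms)
    if (!all(dim(m) == c(nf, nb * nd)))
      stop(sprintf("invalid study container: views/%s/velocity.csv has wrong shape",
                   nm))
    vel <- aperm(array(t(m), dim = c(nd, nb, nf)), c(3L, 2L, 1L))
    ov <- g$avc_override_ms
    ov <- if (is.null(ov) || !length(ov)) NA_real_ else as.numeric(ov)
    views[[nm]] <- viewRecording(g$view_id, vel, g$beam_angles_deg,
                                 g$depths_mm, timing$frame_times_ms,
                                 timing$r_wave_times_ms, ov)
    tp <- data.table::fread(file.path(dir, "traces", paste0(nm, ".csv")))
    tj <- jsonlite::read_json(file.path(dir, "traces", paste0(nm, ".json")),
                              simplifyVector = TRUE)
    traces[[nm]] <- wallTrace(tj$view_id, cbind(tp$x_mm, tp$y_mm),
                              apexIndex = tj$apex_index,
                              referenceFrame = tj$reference_frame)
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth", "kinematics.csv"))) {
    td <- file.path(dir, "truth")
    kin <- as.data.frame(data.table::fread(file.path(td, "kinematics.csv")))
    meta <- jsonlite::read_json(file.path(td, "meta.json"),
                                simplifyVector = TRUE)
    st <- as.data.frame(data.table::fread(file.path(td, "strain.csv")))
    vol <- as.data.frame(data.table::fread(file.path(td, "volume.csv")))
    truth <- new("PhantomTruth",
                 kinematics = kin,
                 trueAvcMs = meta$true_avc_ms,
                 referenceCycleStartMs = meta$reference_cycle_start_ms,
                 strain = as.matrix(st[, paste0("seg_", 1:16)]),
                 volume = vol$volume_mm3,
                 frameTimes = st$time_ms,
                 config = phantomConfig())
  }
  lvStudy(views, traces, truth)
}

#' Export per-segment traces as tidy CSV
#'
#' One row per study x segment x frame:
#' `study, segment, frame_time_ms, strain_pct, sr_per_s, flags`.
#'
#' @param report a [StudyReport-class].
#' @param file target CSV path.
#' @param studyId study identifier written into the `study` column.
#' @return `file`, invisibly.
#' @export
writeTraceCSV <- function(report, file, studyId = "study") {
  rows <- lapply(seq_along(report@traces), function(s) {
    tr <- report@traces[[s]]
    data.table::data.table(
      study = studyId, segment = s, frame_time_ms = tr$timeMs,
      strain_pct = tr$strainPct, sr_per_s = tr$srPerS,
      flags = ifelse(tr$lowQuality, "low_quality", ""))
  })
  data.table::fwrite(data.table::rbindlist(rows), file)
  invisible(file)
}

#' Export the per-segment metrics table as CSV
#'
#' @param report a [StudyReport-class].
#' @param file target CSV path.
#' @param studyId study identifier written into the `study` column.
#' @return `file`, invisibly.
#' @export
writeMetricsCSV <- function(report, file, studyId = "study") {
  m <- cbind(data.frame(study = studyId), report@segments)
  data.table::fwrite(data.table::as.data.table(m), file)
  invisible(file)
}

#' Write / read a pipeline configuration as JSON
#'
#' The dump -> load round trip reproduces the configuration exactly, so a
#' stored config file reproduces the analysis.
#'
#' @param config a [PipelineConfig-class].
#' @param file JSON path.
#' @return `file` (write) / a [PipelineConfig-class] (read).
#' @export
writeConfig <- function(config, file) {
  stopifnot(is(config, "PipelineConfig"))
  sl <- slotNames(config)
  vals <- lapply(sl, function(s) slot(config, s))
  names(vals) <- sl
  jsonlite::write_json(vals, file, digits = NA, auto_unbox = FALSE)
  invisible(file)
}

#' @rdname writeConfig
#' @export
readConfig <- function(file) {
  vals <- jsonlite::read_json(file, simplifyVector = TRUE)
  vals$smoothStrain <- as.logical(vals$smoothStrain)
  vals$smoothSR <- as.logical(vals$smoothSR)
  vals$rejectNoisy <- as.logical(vals$rejectNoisy)
  do.call(pipelineConfig, vals)
}
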
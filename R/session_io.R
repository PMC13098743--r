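# Session-bundle readers/writers and configuration round-tripping. A bundle
# is a directory of plain-text files: meta.json, events.csv, bloodgas.csv,
# vitals.csv, masks.csv and per-location optical CSV tables. Doubles are
# written with repr round-trip precision (%.17g); counts are integers.

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 2^53, sprintf("%.0f", x),
                sprintf("%.17g", x)))
}

.write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.write_matrix <- function(m, lead, path) {
  df <- cbind(lead, as.data.frame(m))
  names(df) <- c(names(lead), paste0("v", seq_len(ncol(m))))
  .write_table(df, path)
}

#' Write a session bundle to a directory
#'
#' @param bundle a `session_bundle`.
#' @param path target directory (created if missing).
#' @return `path`, invisibly.
#' @seealso [read_bundle()] for the lossless inverse.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(subject_id = bundle$subject_id, geometry = bundle$geometry,
               meta = bundle$meta, format_version = "1.0",
               locations = names(bundle$trs),
               package_version = as.character(utils::packageVersion("rbctdo")))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .write_table(bundle$events, file.path(path, "events.csv"))
  .write_table(as.data.frame(bundle$bloodgas), file.path(path, "bloodgas.csv"))
  .write_table(bundle$vitals, file.path(path, "vitals.csv"))
  .write_table(as.data.frame(bundle$masks), file.path(path, "masks.csv"))
  for (loc in names(bundle$trs)) {
    trs <- bundle$trs[[loc]]
    for (wl in names(trs$counts)) {
      .write_matrix(trs$counts[[wl]],
                    data.frame(timestamp_s = trs$time),
                    file.path(path, sprintf("trs_%s_%s.csv", loc, wl)))
      .write_table(data.frame(bin_ps = trs$bin_ps,
                              counts = trs$irf[[wl]]),
                   file.path(path, sprintf("irf_%s_%s.csv", loc, wl)))
    }
    dcs <- bundle$dcs[[loc]]
    .write_matrix(dcs$g2, data.frame(timestamp_s = dcs$time,
                                     count_rate_khz = dcs$count_rate_khz),
                  file.path(path, sprintf("dcs_%s.csv", loc)))
    .write_table(data.frame(tau_s = dcs$tau),
                 file.path(path, sprintf("tau_%s.csv", loc)))
  }
  invisible(path)
}

.need_file <- function(path, name) {
  f <- file.path(path, name)
  if (!file.exists(f))
    stop("session bundle at '", path, "' is missing required file '", name,
         "'")
  f
}

#' Read a session bundle from a directory
#'
#' Schema-validated, lossless inverse of [write_bundle()]. Percent-scale
#' SaO2 columns are left untouched here; conversion happens during
#' [synchronize()].
#'
#' @param path bundle directory.
#' @return a `session_bundle`.
#' @export
read_bundle <- function(path) {
  meta <- jsonlite::read_json(.need_file(path, "meta.json"),
                              simplifyVector = TRUE)
  events <- utils::read.csv(.need_file(path, "events.csv"))
  if (!all(c("time", "label") %in% names(events)))
    stop("events.csv must have columns time,label")
  bgdf <- utils::read.csv(.need_file(path, "bloodgas.csv"))
  bg <- blood_gas(bgdf$time, bgdf$period, bgdf$hgb, bgdf$hct,
                  as.numeric(bgdf$paco2), as.numeric(bgdf$hgbo2),
                  as.numeric(bgdf$hgbr))
  vitals <- utils::read.csv(.need_file(path, "vitals.csv"))
  mk <- utils::read.csv(.need_file(path, "masks.csv"))
  masks <- if (nrow(mk)) artifact_mask(mk$t_start, mk$t_end, mk$source)
  else artifact_mask(numeric(), numeric())
  trs <- list(); dcs <- list()
  for (loc in meta$locations) {
    counts <- list(); irf <- list(); bin_ps <- NA_real_; tt <- NULL
    for (wl in c("690", "830")) {
      cm <- utils::read.csv(.need_file(path, sprintf("trs_%s_%s.csv", loc,
                                                     wl)))
      tt <- cm$timestamp_s
      counts[[wl]] <- as.matrix(cm[, -1, drop = FALSE])
      dimnames(counts[[wl]]) <- NULL
      ir <- utils::read.csv(.need_file(path, sprintf("irf_%s_%s.csv", loc,
                                                     wl)))
      irf[[wl]] <- ir$counts
      bin_ps <- ir$bin_ps[1]
    }
    trs[[loc]] <- list(time = tt, bin_ps = bin_ps, wavelengths = c(690, 830),
                       irf = irf, counts = counts)
    dm <- utils::read.csv(.need_file(path, sprintf("dcs_%s.csv", loc)))
    tau <- utils::read.csv(.need_file(path, sprintf("tau_%s.csv", loc)))$tau_s
    g2 <- as.matrix(dm[, -(1:2), drop = FALSE])
    dimnames(g2) <- NULL
    if (ncol(g2) != length(tau))
      stop("dcs_", loc, ".csv column count does not match tau grid")
    dcs[[loc]] <- list(time = dm$timestamp_s, tau = tau,
                       count_rate_khz = dm$count_rate_khz, g2 = g2)
  }
  structure(list(subject_id = meta$subject_id,
                 geometry = meta$geometry, trs = trs, dcs = dcs,
                 vitals = vitals, bloodgas = bg, events = events,
                 masks = masks, meta = meta$meta),
            class = "session_bundle")
}

#' Write / read a run configuration as YAML
#'
#' @param config an [rbct_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` an
#'   [rbct_config()].
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  raw$directions <- as.list(raw$directions)  # keep names in the YAML map
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- rbct_config()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    cfg[[nm]] <- if (nm == "directions") unlist(v) else
      if (is.list(v)) unlist(v) else v
  }
  cfg
}

#' Export derived traces and QC table of a processed session
#'
#' Derived time series are written as tidy CSV (timestamp, location,
#' variable, value) and the QC table as CSV; the constants in force are
#' echoed into a run-metadata JSON.
#'
#' @param session a processed `subject_session`.
#' @param path target directory.
#' @param config the [rbct_config()] used.
#' @return `path`, invisibly.
#' @export
write_session_outputs <- function(session, path, config = rbct_config()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tidy <- do.call(rbind, lapply(names(session$traces), function(nm) {
    tr <- session$traces[[nm]]
    data.frame(timestamp = tr$time,
               location = attr(tr, "location") %||% NA_character_,
               variable = attr(tr, "variable") %||% nm, value = tr$value)
  }))
  .write_table(tidy, file.path(path, "derived_traces.csv"))
  if (!is.null(session$qc))
    .write_table(session$qc, file.path(path, "qc_table.csv"))
  jsonlite::write_json(
    list(subject_id = session$subject_id, config = unclass(config),
         hct_imputed = session$hct_imputed),
    file.path(path, "run_metadata.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
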
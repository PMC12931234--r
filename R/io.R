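## Guess the delimiter of a text table among comma / tab / semicolon.
detect_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stop("empty file: ", path, call. = FALSE)
  counts <- c("," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              "\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))),
              ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))))
  if (all(counts == 0L)) stop("could not detect a delimiter in ", path, call. = FALSE)
  names(counts)[which.max(counts)]
}

#' Read a ThT plate file (long or wide layout)
#'
#' Reads a delimited text file (comma, tab or semicolon; auto-detected)
#' holding ThT progress curves. Two layouts are supported and
#' auto-detected:
#'
#' * long: columns `well_id`, `time_h`, `fluorescence`, optionally
#'   `condition`, `bio_rep`, `tech_rep`;
#' * wide: a `time_h` column plus one column per well.
#'
#' Time must be in hours (columns named `time_min`/`time_s` are converted
#' on ingest). Rows with unparseable values are reported with their line
#' numbers.
#'
#' @param path Path to the file.
#' @return Long data frame with at least `well_id`, `time_h`,
#'   `fluorescence`, sorted by well and time.
#' @export
read_plate <- function(path) {
  delim <- detect_delim(path)
  d <- read.table(path, sep = delim, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(d) == 0L) stop("no data rows in ", path, call. = FALSE)
  nm <- names(d)
  tcol <- intersect(c("time_h", "time_min", "time_s"), nm)
  if (length(tcol) == 0L) stop("missing time column (time_h/time_min/time_s)",
                               call. = FALSE)
  tcol <- tcol[1L]
  fac <- switch(tcol, time_h = 1, time_min = 1 / 60, time_s = 1 / 3600)
  d$time_h <- suppressWarnings(as.numeric(d[[tcol]])) * fac
  bad <- which(is.na(d$time_h))
  if (length(bad))
    stop("unparseable time values at data line(s) ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)

  if ("fluorescence" %in% nm) {  # long layout
    out <- d[, intersect(c("well_id", "condition", "bio_rep", "tech_rep",
                           "time_h", "fluorescence"), names(d))]
    if (!"well_id" %in% names(out)) out$well_id <- "well1"
    out$fluorescence <- suppressWarnings(as.numeric(out$fluorescence))
    bad <- which(is.na(out$fluorescence))
    if (length(bad))
      stop("unparseable fluorescence at data line(s) ",
           paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  } else {  # wide layout: every non-time column is a well
    wells <- setdiff(nm, c(tcol, "time_h"))
    if (length(wells) == 0L) stop("wide layout needs well columns", call. = FALSE)
    out <- do.call(rbind, lapply(wells, function(w) {
      data.frame(well_id = w, time_h = d$time_h,
                 fluorescence = suppressWarnings(as.numeric(d[[w]])),
                 stringsAsFactors = FALSE)
    }))
    bad <- which(is.na(out$fluorescence))
    if (length(bad))
      stop("unparseable fluorescence values in wide table", call. = FALSE)
  }
  out <- out[order(out$well_id, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a DLS autocorrelation series
#'
#' Reads a delimited file with columns `lag_s`, `g2m1`, `incubation_h`
#' and splits it into a named list of traces keyed by incubation time.
#'
#' @param path Path to the file.
#' @return Named list of data frames (`lag_s`, `g2m1`).
#' @export
read_acf_series <- function(path) {
  delim <- detect_delim(path)
  d <- read.table(path, sep = delim, header = TRUE, stringsAsFactors = FALSE)
  need <- c("lag_s", "g2m1", "incubation_h")
  if (!all(need %in% names(d)))
    stop("ACF file needs columns ", paste(need, collapse = ", "), call. = FALSE)
  sp <- split(d[, c("lag_s", "g2m1")], d$incubation_h)
  sp[order(as.numeric(names(sp)))]
}

#' Write a kinetic trajectory as tidy CSV
#'
#' Columns carry their units in the header (`time_h`; the mass fractions
#' and particle number are dimensionless).
#'
#' @param trajectory A `kin_trajectory` from [simulate_kinetics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory)[, c("time_h", "m", "alpha", "alpha1",
                                          "alpha2", "p")],
            path, row.names = FALSE)
  invisible(path)
}

#' Run the ThT (and optionally joint) analysis pipeline
#'
#' Drives the full analysis from a configuration list or YAML file:
#' reads (or generates) a plate, fits every curve with
#' [fit_progress_curve()], summarises conditions, optionally runs
#' [fit_joint()] against DLS share observations, and writes
#' `fits.csv`, `summary.csv` and `result.json` into the output directory.
#' Outputs embed the seed, the package version and a hash of the
#' configuration, and reruns with the same configuration are identical.
#'
#' Configuration fields: `seed` (integer), `out_dir`; either `plate_path`
#' (file read with [read_plate()]) or `generate = TRUE` (plate from
#' [generator_spec()] defaults); optionally `joint` with `dls_path` or
#' generated shares, `radii = c(r_monomer, r2, r1)` and `small_fraction`.
#'
#' @param config A list or path to a YAML file.
#' @return List with `fits`, `summary`, `joint` (or NULL), `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$plate_path)) {
    if (!file.exists(config$plate_path))
      stop("[read-plate] input path does not exist: ", config$plate_path,
           call. = FALSE)
    plate <- read_plate(config$plate_path)
  } else if (isTRUE(config$generate)) {
    plate <- generate_tht_plate(generator_spec(seed = seed))$plate
  } else stop("[config] need plate_path or generate = TRUE", call. = FALSE)

  fits <- do.call(rbind, lapply(split(plate, plate$well_id), function(cv) {
    f <- fit_progress_curve(cv[, c("time_h", "fluorescence")])
    data.frame(well_id = cv$well_id[1L],
               condition = if ("condition" %in% names(cv)) cv$condition[1L] else "all",
               bio_rep = if ("bio_rep" %in% names(cv)) cv$bio_rep[1L] else 1L,
               t50 = f$t50, v50 = f$v50, se_t50 = f$se_t50, se_v50 = f$se_v50,
               rss = f$rss, flag = f$flag, stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  smry <- tryCatch(summarize_conditions(fits), error = function(e) NULL)

  joint <- NULL
  if (!is.null(config$joint)) {
    jc <- config$joint
    dls <- read.table(jc$dls_path, sep = detect_delim(jc$dls_path),
                      header = TRUE)
    radii <- if (is.null(jc$radii)) c(3, 15, 150) else as.numeric(jc$radii)
    ds <- joint_dataset(plate[, c("well_id", "time_h", "fluorescence")], dls,
                        r_monomer = radii[1L], r2 = radii[2L], r1 = radii[3L],
                        small_fraction = if (is.null(jc$small_fraction)) 0.5
                                         else jc$small_fraction)
    joint <- fit_joint(ds, seed = seed)
  }

  meta <- list(seed = seed,
               package_version = as.character(utils::packageVersion("aggrekin")),
               config_hash = config_hash(config))
  paths <- list(fits = file.path(config$out_dir, "fits.csv"),
                summary = file.path(config$out_dir, "summary.csv"),
                result = file.path(config$out_dir, "result.json"))
  write.csv(fits, paths$fits, row.names = FALSE)
  if (!is.null(smry)) write.csv(smry, paths$summary, row.names = FALSE)
  res <- c(meta, list(
    n_curves = nrow(fits),
    conditions = if (!is.null(smry)) smry else NULL,
    joint = if (!is.null(joint)) list(
      rate_products_h = as.list(coef(joint)),
      se_h = as.list(joint$se),
      radii_nm = c(joint$params$r_monomer, joint$params$r2, joint$params$r1),
      regime = classify_regime(joint)$label) else NULL))
  jsonlite::write_json(res, paths$result, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  list(fits = fits, summary = smry, joint = joint, paths = paths)
}

## Stable hash of the configuration: md5 of its canonical JSON form.
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile(); on.exit(unlink(f))
  writeLines(js, f)
  unname(tools::md5sum(f))
}
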
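# File formats: delimited DVH tables, MU tables, plain-text dose grids,
# a minimal DICOM RT Dose codec (explicit VR little endian, axis-aligned,
# uniform frame spacing), YAML plan manifests and JSON reports.

#' Read and write DVH tables
#'
#' The DVH text dialect is a delimited table with a `dose_gy,volume` header
#' preceded by metadata lines `# structure=`, `# kind=` (cumulative or
#' differential) and `# volume_units=` (fraction, percent, or cc -- cc
#' requires an additional `# total_cc=` line used to normalize to
#' fractions). Readers validate rather than coerce: non-monotone cumulative
#' volumes are rejected with the offending row number.
#'
#' @param path file path.
#' @return `read_dvh_table()` returns a [dvh] (volumes normalized to
#'   fractions).
#' @export
read_dvh_table <- function(path) {
  if (!file.exists(path))
    ds_validation_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  if (is.null(meta$kind))
    ds_validation_error("DVH file is missing the '# kind=' metadata line")
  if (!meta$kind %in% c("cumulative", "differential"))
    ds_validation_error(sprintf("unknown DVH kind '%s'", meta$kind))
  units <- if (is.null(meta$volume_units)) "fraction" else meta$volume_units
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L || !grepl("^dose_gy\\s*,\\s*volume", body[1L]))
    ds_validation_error("DVH file is missing the 'dose_gy,volume' header")
  tab <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  vol <- tab$volume
  if (units == "percent") {
    vol <- vol / 100
  } else if (units == "cc") {
    if (is.null(meta$total_cc))
      ds_validation_error("volume_units=cc requires a '# total_cc=' line")
    vol <- vol / as.numeric(meta$total_cc)
  } else if (units != "fraction") {
    ds_validation_error(sprintf("unknown volume_units '%s'", units))
  }
  if (meta$kind == "cumulative") {
    bad <- which(diff(vol) > 1e-9)
    if (length(bad))
      ds_validation_error(sprintf(
        "cumulative volume increases at data row %d", bad[1L] + 1L))
  }
  dvh(tab$dose_gy, vol, kind = meta$kind,
      structure = if (is.null(meta$structure)) "structure" else meta$structure)
}

#' @rdname read_dvh_table
#' @param x a [dvh] to write.
#' @param volume_units `"fraction"` or `"percent"` for output.
#' @export
write_dvh_table <- function(x, path, volume_units = "fraction") {
  stopifnot(inherits(x, "dvh"))
  if (!volume_units %in% c("fraction", "percent"))
    ds_domain_error("write supports volume_units 'fraction' or 'percent'")
  v <- if (volume_units == "percent") 100 * x$volume else x$volume
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# structure=%s", x$structure),
    sprintf("# kind=%s", x$kind),
    sprintf("# volume_units=%s", volume_units),
    "dose_gy,volume",
    sprintf("%.12g,%.12g", x$dose, v)
  ), con)
  invisible(path)
}

#' Read and write beam monitor-unit tables
#'
#' Two-column delimited text (`beam_id,mu`), order preserved. Duplicate
#' beam ids and non-positive MUs are rejected.
#'
#' @param path file path.
#' @return `read_mu_table()` returns a data.frame with columns `beam_id`
#'   and `mu`.
#' @export
read_mu_table <- function(path) {
  if (!file.exists(path))
    ds_validation_error(sprintf("no such file: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("beam_id", "mu") %in% names(tab)))
    ds_validation_error("MU table needs columns beam_id,mu")
  if (anyDuplicated(tab$beam_id))
    ds_validation_error("duplicate beam_id in MU table")
  if (anyNA(tab$mu) || any(tab$mu <= 0))
    ds_validation_error("all MU values must be > 0")
  data.frame(beam_id = as.character(tab$beam_id), mu = as.numeric(tab$mu))
}

#' @rdname read_mu_table
#' @param beams data.frame with `beam_id` and `mu`.
#' @export
write_mu_table <- function(beams, path) {
  utils::write.csv(beams[, c("beam_id", "mu")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and write plain-text dose grids
#'
#' Header lines `# shape=`, `# spacing_mm=`, `# origin_mm=` (comma
#' separated per axis) followed by the dose values in row-major order
#' (within a slice: rows, then columns; slices sequential for 3D).
#'
#' @param path file path.
#' @return `read_dose_grid_text()` returns a [dose_grid].
#' @export
read_dose_grid_text <- function(path) {
  if (!file.exists(path))
    ds_validation_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (length(ln) != 1L)
      ds_validation_error(sprintf("dose grid file is missing '# %s='", key))
    as.numeric(strsplit(sub(".*=", "", ln), ",")[[1L]])
  }
  shp <- as.integer(get("shape"))
  spacing <- get("spacing_mm")
  origin <- get("origin_mm")
  vals <- scan(text = paste(lines[!grepl("^#", lines)], collapse = " "),
               quiet = TRUE)
  if (length(vals) != prod(shp))
    ds_validation_error(sprintf("expected %d values, found %d",
                                prod(shp), length(vals)))
  # stored row-major (last axis fastest); R arrays are column-major
  arr <- aperm(array(vals, rev(shp)), rev(seq_along(shp)))
  dose_grid(arr, spacing = spacing, origin = origin)
}

#' @rdname read_dose_grid_text
#' @param grid a [dose_grid] to write.
#' @export
write_dose_grid_text <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  shp <- dim(grid$values)
  vals <- as.vector(aperm(grid$values, rev(seq_along(shp))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# shape=%s", paste(shp, collapse = ",")),
    sprintf("# spacing_mm=%s", paste(format(grid$spacing, digits = 12), collapse = ",")),
    sprintf("# origin_mm=%s", paste(format(grid$origin, digits = 12), collapse = ","))
  ), con)
  writeLines(paste(format(vals, digits = 12, trim = TRUE, scientific = FALSE),
                   collapse = " "), con)
  invisible(path)
}

## ---- minimal DICOM RT Dose codec (explicit VR little endian) ----

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                   endian = "little")
dcm_uint32 <- function(x) {
  x <- as.numeric(x)
  x[x >= 2^31] <- x[x >= 2^31] - 2^32
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

dcm_element <- function(group, elem, vr, payload) {
  if (is.character(payload)) {
    payload <- charToRaw(payload)
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    if (length(payload) %% 2L == 1L) payload <- c(payload, pad)
  }
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(dcm_uint16(c(group, elem)), charToRaw(vr),
    if (long_vr) c(as.raw(c(0, 0)), dcm_uint32(length(payload)))
    else dcm_uint16(length(payload)),
    payload)
}

#' Write a DICOM RT Dose file
#'
#' Serializes a [dose_grid] as a DICOM RT Dose object (explicit VR little
#' endian, 32-bit unsigned pixel data, axis-aligned orientation, uniform
#' frame offsets). Doses are stored as integers scaled by the dose-grid
#' scaling tag; the default scaling maps the grid maximum onto the full
#' 32-bit range, so the quantization error is at most `scaling / 2`.
#'
#' @param grid a [dose_grid] (2D grids are written as a single frame).
#' @param path output path.
#' @param scaling dose-grid scaling in Gy per stored unit; default chosen
#'   from the grid maximum.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(grid, path, scaling = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  v <- grid$values
  if (length(dim(v)) == 2L) v <- array(v, c(dim(v), 1L))
  spacing <- grid$spacing
  origin <- grid$origin
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (length(origin) == 2L) origin <- c(origin, 0)
  if (is.null(scaling))
    scaling <- if (max(v) > 0) max(v) / (2^32 - 1) else 1.0
  stored <- round(v / scaling)
  if (any(stored > 2^32 - 1))
    ds_validation_error("scaling too small for the dose range")
  d <- dim(v)
  ds <- function(x) paste(format(x, digits = 15, trim = TRUE,
                                 scientific = FALSE), collapse = "\\")
  offsets <- (seq_len(d[3L]) - 1L) * spacing[3L]
  pix <- dcm_uint32(as.vector(aperm(stored, c(2, 1, 3))))

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.481.2"),
    dcm_element(0x0002, 0x0003, "UI", "1.2.826.0.1.3680043.9.7435.1.1"),
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7435.0.1")
  )
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.2"),
    dcm_element(0x0008, 0x0018, "UI", "1.2.826.0.1.3680043.9.7435.1.1"),
    dcm_element(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_element(0x0020, 0x0032, "DS", ds(origin)),
    dcm_element(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_element(0x0028, 0x0002, "US", dcm_uint16(1)),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0008, "IS", as.character(d[3L])),
    dcm_element(0x0028, 0x0010, "US", dcm_uint16(d[1L])),
    dcm_element(0x0028, 0x0011, "US", dcm_uint16(d[2L])),
    dcm_element(0x0028, 0x0030, "DS", ds(spacing[1:2])),
    dcm_element(0x0028, 0x0100, "US", dcm_uint16(32)),
    dcm_element(0x0028, 0x0101, "US", dcm_uint16(32)),
    dcm_element(0x0028, 0x0102, "US", dcm_uint16(31)),
    dcm_element(0x0028, 0x0103, "US", dcm_uint16(0)),
    dcm_element(0x3004, 0x0002, "CS", "GY"),
    dcm_element(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_element(0x3004, 0x000A, "CS", "PLAN"),
    dcm_element(0x3004, 0x000C, "DS", ds(offsets)),
    dcm_element(0x3004, 0x000E, "DS", ds(scaling)),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_element(0x0002, 0x0000, "UL", dcm_uint32(length(meta))), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

#' Read a DICOM RT Dose file
#'
#' Reads the dialect this package writes and typical axis-aligned
#' single-dose exports: explicit VR little endian, uncompressed 16- or
#' 32-bit unsigned pixel data, identity orientation, uniform frame
#' offsets. Pixel data times the dose-grid scaling tag gives Gy; spacing
#' comes from pixel spacing and the frame offsets, the origin from the
#' image position. Missing required tags and unsupported dialects are
#' rejected with the offending tag named.
#'
#' @param path file path.
#' @return A [dose_grid] (3D; single-frame files give a `dim[3] == 1`
#'   array collapsed to 2D).
#' @export
read_rtdose <- function(path) {
  if (!file.exists(path))
    ds_validation_error(sprintf("no such file: %s", path))
  n <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, raw(), n)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    ds_validation_error("not a DICOM file (missing DICM magic)")
  pos <- 133L
  tags <- list()
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) as.integer(bytes[i]) + 256 * as.integer(bytes[i + 1L]) +
    65536 * as.integer(bytes[i + 2L]) + 16777216 * as.integer(bytes[i + 3L])
  while (pos + 8L <= length(bytes) + 1L) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(pos + 6L)
      hdr <- 8L
    }
    if (vr == "SQ")
      ds_validation_error("sequence elements are not supported by this reader")
    payload_start <- pos + hdr
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, start = payload_start, len = len)
    pos <- payload_start + len
  }
  need <- function(key, what) {
    t <- tags[[key]]
    if (is.null(t))
      ds_validation_error(sprintf("missing DICOM tag (%s) %s", key, what))
    t
  }
  get_str <- function(t) trimws(rawToChar(bytes[t$start:(t$start + t$len - 1L)]))
  get_ds <- function(t) as.numeric(strsplit(get_str(t), "\\\\")[[1L]])
  get_us <- function(t) u16(t$start)

  rows <- get_us(need("0028,0010", "Rows"))
  cols <- get_us(need("0028,0011", "Columns"))
  nframes <- if (!is.null(tags[["0028,0008"]]))
    as.integer(get_str(tags[["0028,0008"]])) else 1L
  spacing_rc <- get_ds(need("0028,0030", "PixelSpacing"))
  origin <- if (!is.null(tags[["0020,0032"]]))
    get_ds(tags[["0020,0032"]]) else c(0, 0, 0)
  if (!is.null(tags[["0020,0037"]])) {
    orient <- get_ds(tags[["0020,0037"]])
    if (max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-9)
      ds_validation_error(
        "non-axis-aligned ImageOrientationPatient (0020,0037) is unsupported")
  }
  scaling <- get_ds(need("3004,000E", "DoseGridScaling"))
  dz <- 1
  if (nframes > 1L) {
    offs <- get_ds(need("3004,000C", "GridFrameOffsetVector"))
    if (length(offs) != nframes)
      ds_validation_error("GridFrameOffsetVector (3004,000C) length mismatch")
    steps <- diff(offs)
    if (max(abs(steps - steps[1L])) > 1e-9)
      ds_validation_error(
        "non-uniform GridFrameOffsetVector (3004,000C) is unsupported")
    dz <- steps[1L]
  }
  bits <- get_us(need("0028,0100", "BitsAllocated"))
  if (!bits %in% c(16L, 32L))
    ds_validation_error("only 16- or 32-bit pixel data (0028,0100) supported")
  pix <- need("7FE0,0010", "PixelData")
  npx <- rows * cols * nframes
  if (pix$len < npx * bits / 8)
    ds_validation_error("PixelData (7FE0,0010) shorter than Rows*Columns*Frames")
  pr <- bytes[pix$start:(pix$start + npx * bits / 8 - 1L)]
  if (bits == 16L) {
    stored <- readBin(pr, integer(), n = npx, size = 2, signed = FALSE,
                      endian = "little")
    stored <- as.numeric(stored)
  } else {
    stored <- readBin(pr, integer(), n = npx, size = 4, endian = "little")
    stored <- as.numeric(stored)
    stored[stored < 0] <- stored[stored < 0] + 2^32
  }
  arr <- aperm(array(stored * scaling, c(cols, rows, nframes)), c(2, 1, 3))
  if (nframes == 1L) {
    dose_grid(arr[, , 1L], spacing = spacing_rc, origin = origin[1:2])
  } else {
    dose_grid(arr, spacing = c(spacing_rc, dz), origin = origin)
  }
}

## ---- plan manifests and reports ----

#' Read and write plan manifests
#'
#' A plan manifest is a small YAML file naming the plan's algorithm, dose
#' mode, prescription and isocentre dose, plus relative paths to the MU
#' table, the per-structure DVH files, and optionally a dose grid (text or
#' DICOM RT Dose). `write_plan_manifest()` writes the manifest and all
#' referenced files into a directory; `read_plan_manifest()` reconstructs
#' the [plan_record].
#'
#' @param plan a [plan_record].
#' @param dir directory to write into (created if missing).
#' @param name base name for the manifest (default the plan label).
#' @param grid_format `"text"` or `"dicom"` for the dose grid.
#' @return The manifest path.
#' @export
write_plan_manifest <- function(plan, dir, name = plan$label,
                                grid_format = c("text", "dicom")) {
  stopifnot(inherits(plan, "plan_record"))
  grid_format <- match.arg(grid_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mu_file <- paste0(name, "_mu.csv")
  write_mu_table(plan$beams, file.path(dir, mu_file))
  dvh_files <- list()
  for (s in names(plan$dvhs)) {
    f <- sprintf("%s_dvh_%s.csv", name, gsub("[^A-Za-z0-9_]", "_", s))
    write_dvh_table(plan$dvhs[[s]], file.path(dir, f))
    dvh_files[[s]] <- f
  }
  manifest <- list(
    label = plan$label, algorithm = plan$algorithm,
    dose_mode = plan$dose_mode, dpr = plan$dpr, diso = plan$diso,
    mu_table = mu_file, dvhs = dvh_files
  )
  if (!is.null(plan$dose_grid)) {
    gf <- if (grid_format == "text") paste0(name, "_dose.txt")
          else paste0(name, "_dose.dcm")
    if (grid_format == "text")
      write_dose_grid_text(plan$dose_grid, file.path(dir, gf))
    else
      write_rtdose(plan$dose_grid, file.path(dir, gf))
    manifest$dose_grid <- list(file = gf, format = grid_format)
  }
  path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(manifest, path)
  path
}

#' @rdname write_plan_manifest
#' @param path manifest path to read.
#' @export
read_plan_manifest <- function(path) {
  if (!file.exists(path))
    ds_validation_error(sprintf("no such file: %s", path))
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  need <- c("label", "algorithm", "dpr", "diso", "mu_table")
  miss <- setdiff(need, names(m))
  if (length(miss))
    ds_validation_error(sprintf("manifest is missing: %s",
                                paste(miss, collapse = ", ")))
  beams <- read_mu_table(file.path(dir, m$mu_table))
  dvhs <- list()
  for (s in names(m$dvhs))
    dvhs[[s]] <- read_dvh_table(file.path(dir, m$dvhs[[s]]))
  grid <- NULL
  if (!is.null(m$dose_grid)) {
    gp <- file.path(dir, m$dose_grid$file)
    grid <- if (identical(m$dose_grid$format, "dicom")) read_rtdose(gp)
            else read_dose_grid_text(gp)
  }
  plan_record(label = m$label, algorithm = m$algorithm, dpr = m$dpr,
              diso = m$diso, beams = beams, dvhs = dvhs, dose_grid = grid,
              dose_mode = if (is.null(m$dose_mode)) "Dw" else m$dose_mode)
}

#' Export a transition report as machine-readable JSON
#'
#' Writes the numeric content of a [transition_report][compare_plans] --
#' run metadata, MU deltas, DVH deltas, gamma pass rates, statistics and
#' the decision -- to JSON.
#'
#' @param report a `transition_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "transition_report"))
  out <- list(
    meta = list(
      package = "doseshift",
      version = as.character(utils::packageVersion("doseshift")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      algorithms = c(reference = report$plan1$algorithm,
                     tested = report$plan2$algorithm),
      rules = list(
        d95_tolerance_percent = report$rules$d95_tolerance_percent,
        gamma_pass_goal = report$rules$gamma_pass_goal,
        alpha = report$rules$alpha,
        gamma_criteria = vapply(report$rules$gamma_criteria_list,
                                format, ""))
    ),
    dpr = report$dpr,
    delta_mu = list(per_beam = report$delta_mu$per_beam,
                    total = report$delta_mu$total,
                    total_pct = report$delta_mu$total_pct),
    plan3 = list(diso = report$plan3$diso,
                 target_eud = report$plan3_target_eud,
                 target_d95 = report$plan3_target_d95),
    d95_delta_pct = report$d95_delta_pct,
    dvh_deltas_plan2 = report$dvh_deltas_plan2$table,
    dvh_deltas_plan3 = report$dvh_deltas_plan3$table,
    gamma_pass_rates = as.list(report$gamma_pass_rates),
    stats = report$stats[c("p_value", "statistic", "n_used", "rho")],
    decision = unclass(report$decision)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
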
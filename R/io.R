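# CSV readers and writers --------------------------------------------------
#
# File dialects (all plain CSV, fixed units: um, g/cm3, kPa):
#   distribution:  class_midpoint,frequency       (one file per distribution)
#   component lib: name,abbr,role,true_density,bulk_density,psd_file,
#                  ard_file,shape_factor          (files relative to the lib)
#   formulation:   blend_code,api_label,component_abbr,mass_fraction
#   flow:          blend_code,pressure_kpa,ffc
# Numbers are written with 17 significant digits so write -> read round
# trips are value-exact.

fmt_num <- function(x) sprintf("%.17g", x)

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a frequency distribution CSV
#'
#' Expects columns `class_midpoint,frequency`. Raw frequency sums deviating
#' from one by less than `1e-3` are renormalized; larger deviations are
#' refused as data errors.
#'
#' @param path CSV file path.
#' @param kind Grid kind, `"size"` or `"aspect_ratio"`.
#' @param basis Distribution basis.
#' @return A [freq_dist()].
#' @export
read_distribution <- function(path, kind = c("size", "aspect_ratio"),
                              basis = "number") {
  kind <- match.arg(kind)
  df <- read_csv_checked(path, c("class_midpoint", "frequency"))
  if (any(df$frequency < 0)) {
    stop(sprintf("%s: negative frequency at row %d", path,
                 which(df$frequency < 0)[1]), call. = FALSE)
  }
  freq_dist(class_grid(df$class_midpoint, kind), df$frequency, basis = basis)
}

#' Write a frequency distribution CSV
#' @param dist A [freq_dist()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "freq_dist"))
  df <- data.frame(class_midpoint = fmt_num(dist$grid$midpoints),
                   frequency = fmt_num(dist$frequencies))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a component library
#'
#' The library CSV has columns `name,abbr,role,true_density,bulk_density,
#' psd_file,ard_file,shape_factor`; distribution file paths are resolved
#' relative to the library file's directory.
#'
#' @param path Library CSV path.
#' @return A list of [powder_component()] objects.
#' @export
read_component_library <- function(path) {
  df <- read_csv_checked(path, c("name", "abbr", "role", "true_density",
                                 "bulk_density", "psd_file", "ard_file",
                                 "shape_factor"))
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    if (!is.finite(row$true_density) || row$true_density <= 0 ||
        !is.finite(row$bulk_density) || row$bulk_density <= 0) {
      stop(sprintf("component '%s': densities must be positive", row$name),
           call. = FALSE)
    }
    powder_component(
      name = row$name, abbreviation = row$abbr, role = row$role,
      true_density = row$true_density, bulk_density = row$bulk_density,
      psd = read_distribution(file.path(base, row$psd_file), "size"),
      ard = read_distribution(file.path(base, row$ard_file), "aspect_ratio"),
      shape_factor = row$shape_factor)
  })
}

#' Write a component library
#'
#' Writes the library CSV plus one distribution CSV per component per
#' distribution (named `<abbr>_psd.csv` / `<abbr>_ard.csv`) into `dir`.
#'
#' @param components List of [powder_component()] objects.
#' @param dir Output directory (created if absent).
#' @return Path of the library CSV, invisibly.
#' @export
write_component_library <- function(components, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(components, function(cc) {
    psd_file <- paste0(cc$abbreviation, "_psd.csv")
    ard_file <- paste0(cc$abbreviation, "_ard.csv")
    write_distribution(cc$psd, file.path(dir, psd_file))
    write_distribution(cc$ard, file.path(dir, ard_file))
    data.frame(name = cc$name, abbr = cc$abbreviation, role = cc$role,
               true_density = fmt_num(cc$true_density),
               bulk_density = fmt_num(cc$bulk_density),
               psd_file = psd_file, ard_file = ard_file,
               shape_factor = fmt_num(cc$shape_factor))
  })
  path <- file.path(dir, "components.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a formulation table
#'
#' Long-format CSV with columns `blend_code,api_label,component_abbr,
#' mass_fraction`. Rows whose abbreviation is the placeholder `"XXX"`
#' (no-API / no-second-filler slot) are dropped provided their fraction is
#' zero; a non-zero `"XXX"` fraction is an error. Each blend's fractions
#' must sum to one.
#'
#' @param path Formulation CSV path.
#' @return A list of [formulation()] objects.
#' @export
read_formulation_table <- function(path) {
  df <- read_csv_checked(path, c("blend_code", "api_label", "component_abbr",
                                 "mass_fraction"))
  bad_xxx <- df$component_abbr == "XXX" & df$mass_fraction != 0
  if (any(bad_xxx)) {
    stop(sprintf("blend '%s': placeholder component 'XXX' carries non-zero mass fraction",
                 df$blend_code[bad_xxx][1]), call. = FALSE)
  }
  df <- df[df$component_abbr != "XXX", , drop = FALSE]
  lapply(split(df, factor(df$blend_code, levels = unique(df$blend_code))),
         function(b) {
           api <- unique(b$api_label)
           if (length(api) != 1L) {
             stop(sprintf("blend '%s': inconsistent api_label", b$blend_code[1]),
                  call. = FALSE)
           }
           formulation(b$blend_code[1], b$component_abbr, b$mass_fraction,
                       api_label = api)
         })
}

#' Write a formulation table
#' @param formulations List of [formulation()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_formulation_table <- function(formulations, path) {
  rows <- lapply(formulations, function(f) {
    data.frame(blend_code = f$blend_code, api_label = f$api_label,
               component_abbr = f$component_abbrs,
               mass_fraction = fmt_num(f$mass_fractions))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flow-measurement table
#'
#' CSV with columns `blend_code,pressure_kpa,ffc`.
#'
#' @param path Flow CSV path.
#' @return A data frame with one row per measurement.
#' @export
read_flow_table <- function(path) {
  df <- read_csv_checked(path, c("blend_code", "pressure_kpa", "ffc"))
  if (any(df$ffc <= 0) || any(df$pressure_kpa <= 0)) {
    stop(sprintf("%s: ffc and pressure_kpa must be positive", path),
         call. = FALSE)
  }
  df
}

#' Write a flow-measurement table
#' @param flow Data frame with columns `blend_code,pressure_kpa,ffc`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_table <- function(flow, path) {
  df <- data.frame(blend_code = flow$blend_code,
                   pressure_kpa = fmt_num(flow$pressure_kpa),
                   ffc = fmt_num(flow$ffc))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a prediction report
#'
#' One row per blend and consolidation pressure: densities, FFC point
#' prediction and (when available) interval bounds and relative standard
#' deviation. Blends without FFC predictions contribute one row with empty
#' pressure/FFC fields. Numeric values round trip exactly through
#' [read_prediction_report()].
#'
#' @param properties Non-empty list of [mixture_properties()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(properties, path) {
  if (length(properties) == 0L) {
    stop("no mixture properties to report", call. = FALSE)
  }
  rows <- lapply(properties, function(p) {
    base <- data.frame(blend_code = p$blend_code,
                       true_density = fmt_num(p$true_density),
                       bulk_density = fmt_num(p$bulk_density),
                       tapped_density = ifelse(is.na(p$tapped_density), "",
                                               fmt_num(p$tapped_density)))
    ffc <- p$ffc_by_pressure
    if (is.null(ffc) || nrow(ffc) == 0L) {
      return(cbind(base, pressure_kpa = "", ffc = "", ffc_lower = "",
                   ffc_upper = "", ffc_rsd = ""))
    }
    opt <- function(col) if (col %in% names(ffc)) fmt_num(ffc[[col]]) else ""
    cbind(base[rep(1L, nrow(ffc)), , drop = FALSE],
          data.frame(pressure_kpa = fmt_num(ffc$pressure_kpa),
                     ffc = fmt_num(ffc$ffc), ffc_lower = opt("lower"),
                     ffc_upper = opt("upper"), ffc_rsd = opt("rsd")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction report
#' @param path Report CSV path.
#' @return Data frame of the report rows with numeric columns.
#' @export
read_prediction_report <- function(path) {
  read_csv_checked(path, c("blend_code", "true_density", "bulk_density"))
}
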
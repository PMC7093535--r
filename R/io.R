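#' Default species -> charge mapping (elementary-charge units)
#'
#' Na+ and Cl- are the monovalent bath ions; `DNA_charge` is one backbone
#' phosphate site (-1 e per base in the default charge model); `surface_atom`
#' carries whatever per-atom charge spreads the sheet's sigma over its atoms
#' (set when a frame is generated); `other` is inert.
#'
#' @return Named numeric vector, charges in units of e.
#' @export
default_species_charges <- function() {
  c("Na+" = 1, "Cl-" = -1, DNA_charge = -1, surface_atom = 0, other = 0)
}

#' Construct a particle frame
#'
#' A particle frame is a tibble of labelled point particles (one row per
#' particle, columns `species`, `x`, `y`, `z` in nm) carrying the simulation
#' box, the surface model and the species charge map as attributes. It is the
#' container every profile and screening computation starts from.
#'
#' The coordinate convention puts `z = 0` at the mean graphene plane with the
#' solution at larger z; x and y lie in `[0, Lx]` and `[0, Ly]`.
#'
#' @param particles Data frame with columns `species`, `x`, `y`, `z` (nm).
#' @param box Length-3 numeric, box dimensions (Lx, Ly, Lz) in nm. Lz is the
#'   solution extent above the mean plane; the domain additionally dips below
#'   z = 0 where the surface does.
#' @param surface A [surface_model()].
#' @param charges Named numeric vector of charges per species, e units.
#'   Defaults to [default_species_charges()].
#' @param validate Check invariants (finite positions inside the box, every
#'   species charged)? Default TRUE.
#' @return A tibble of class `particle_frame`.
#' @export
particle_frame <- function(particles, box, surface,
                           charges = default_species_charges(),
                           validate = TRUE) {
  stopifnot(is.data.frame(particles), length(box) == 3)
  particles <- tibble::as_tibble(particles)[, c("species", "x", "y", "z")]
  particles$species <- as.character(particles$species)
  out <- structure(particles,
    box = as.numeric(box),
    surface = surface,
    charges = charges,
    class = c("particle_frame", class(tibble::tibble()))
  )
  if (validate) validate_frame(out)
  out
}

validate_frame <- function(frame) {
  box <- attr(frame, "box")
  surface <- attr(frame, "surface")
  charges <- attr(frame, "charges")
  pos <- as.matrix(frame[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("Frame positions must be finite.", call. = FALSE)
  zr <- surface_z_range(surface, box)
  tol <- 1e-6
  inside <- pos[, 1] >= -tol & pos[, 1] <= box[1] + tol &
    pos[, 2] >= -tol & pos[, 2] <= box[2] + tol &
    pos[, 3] >= zr[1] - tol & pos[, 3] <= zr[2] + tol
  if (!all(inside)) {
    stop(sum(!inside), " particle(s) lie outside the box.", call. = FALSE)
  }
  missing_q <- setdiff(unique(frame$species), names(charges))
  if (length(missing_q)) {
    stop("No charge defined for species: ", paste(missing_q, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(frame)
}

#' Total charge of a frame, in elementary charges
#'
#' Sums particle charges from the frame's species charge map. For generated
#' frames this should cancel the surface charge and DNA to within 1 e
#' (global electroneutrality).
#'
#' @param frame A [particle_frame()].
#' @param species Optional character vector restricting the sum.
#' @return Total charge in e.
#' @export
frame_charge <- function(frame, species = NULL) {
  charges <- attr(frame, "charges")
  sp <- frame$species
  if (!is.null(species)) sp <- sp[sp %in% species]
  sum(charges[sp])
}

# ---- extended-XYZ frame i/o ------------------------------------------------

#' Write a particle frame as extended XYZ
#'
#' Line 1 is the particle count; line 2 carries `Properties=species:S:1:pos:R:3`
#' plus `Box="Lx Ly Lz"`, the species charge map and the surface parameters so
#' a frame round-trips without a side-channel config. Coordinates are written
#' to 6 decimals (1 fm resolution at nm units).
#'
#' @param frame A [particle_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  box <- attr(frame, "box")
  charges <- attr(frame, "charges")
  surface <- attr(frame, "surface")
  charge_str <- paste(sprintf("%s=%.10g", names(charges), charges), collapse = ",")
  surf_str <- sprintf(
    "kind=%s,wavelength=%.10g,amplitude=%.10g,trench_radius=%.10g,trench_length=%.10g,trench_x0=%.10g,sigma=%.10g",
    surface$kind, surface$wavelength, surface$amplitude,
    surface$trench_radius, surface$trench_length, surface$trench_x0, surface$sigma
  )
  header <- sprintf(
    'Properties=species:S:1:pos:R:3 Box="%.6f %.6f %.6f" Charges="%s" Surface="%s"',
    box[1], box[2], box[3], charge_str, surf_str
  )
  body <- sprintf("%s %.6f %.6f %.6f", frame$species, frame$x, frame$y, frame$z)
  writeLines(c(as.character(nrow(frame)), header, body), path)
  invisible(path)
}

parse_kv <- function(line, key) {
  m <- regmatches(line, regexec(paste0(key, '="([^"]*)"'), line))[[1]]
  if (length(m) < 2) NULL else m[2]
}

#' Read an extended-XYZ particle frame
#'
#' Strict by default: a malformed coordinate line aborts with its line number,
#' and a species without a charge in the mapping is a configuration error.
#' With `config$unknown_species = "other"` unmapped species are relabelled
#' `other` (charge 0) instead of rejected.
#'
#' @param path File path.
#' @param config Optional list overriding what the file header declares:
#'   `species_charges` (named vector, e units), `box`, `surface` (a
#'   [surface_model()]), `unknown_species` (`"error"` or `"other"`).
#' @return A [particle_frame()].
#' @export
read_frame <- function(path, config = list()) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2) stop("Frame file has no header lines.", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("Line 1: expected a particle count.", call. = FALSE)
  if (length(lines) < 2 + n) {
    stop("Frame file declares ", n, " particles but has ", length(lines) - 2,
      " coordinate lines.",
      call. = FALSE
    )
  }
  header <- lines[2]

  box <- config$box
  if (is.null(box)) {
    bs <- parse_kv(header, "Box")
    if (is.null(bs)) stop("No Box=... in header and none supplied in config.", call. = FALSE)
    box <- as.numeric(strsplit(trimws(bs), "\\s+")[[1]])
  }

  charges <- config$species_charges
  if (is.null(charges)) {
    cs <- parse_kv(header, "Charges")
    if (!is.null(cs)) {
      kv <- strsplit(strsplit(cs, ",")[[1]], "=")
      charges <- stats::setNames(
        vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
        vapply(kv, function(p) p[1], character(1))
      )
    } else {
      charges <- default_species_charges()
    }
  }

  surface <- config$surface
  if (is.null(surface)) {
    ss <- parse_kv(header, "Surface")
    if (!is.null(ss)) {
      kv <- strsplit(strsplit(ss, ",")[[1]], "=")
      vals <- stats::setNames(
        lapply(kv, function(p) p[2]),
        vapply(kv, function(p) p[1], character(1))
      )
      surface <- surface_model(
        kind = vals$kind,
        wavelength = as.numeric(vals$wavelength),
        amplitude = as.numeric(vals$amplitude),
        trench_radius = as.numeric(vals$trench_radius),
        trench_length = as.numeric(vals$trench_length),
        trench_x0 = as.numeric(vals$trench_x0),
        sigma = as.numeric(vals$sigma)
      )
    } else {
      surface <- surface_model("flat")
    }
  }

  body <- lines[2 + seq_len(n)]
  parts <- strsplit(trimws(body), "\\s+")
  bad_len <- which(lengths(parts) != 4)
  if (length(bad_len)) {
    stop("Line ", 2 + bad_len[1], ": expected 'species x y z'.", call. = FALSE)
  }
  species <- vapply(parts, `[[`, character(1), 1)
  coords <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3, byrow = TRUE)
  )
  bad_num <- which(!stats::complete.cases(coords))
  if (length(bad_num)) {
    stop("Line ", 2 + bad_num[1], ": non-numeric coordinate.", call. = FALSE)
  }

  unknown <- setdiff(unique(species), names(charges))
  if (length(unknown)) {
    mode <- config$unknown_species %||% "error"
    if (identical(mode, "other")) {
      species[species %in% unknown] <- "other"
      charges <- c(charges, c(other = 0)[setdiff("other", names(charges))])
    } else {
      stop("Species without a charge mapping: ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }

  particle_frame(
    tibble::tibble(species = species, x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    box = box, surface = surface, charges = charges
  )
}

# ---- delimited tables ------------------------------------------------------

unit_multiplier <- function(unit, kind = c("concentration", "voltage", "current")) {
  kind <- match.arg(kind)
  tab <- switch(kind,
    concentration = c(
      M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
      fM = 1e-15, aM = 1e-18, zM = 1e-21
    ),
    voltage = c(V = 1, mV = 1e-3),
    current = c(A = 1, mA = 1e-3, uA = 1e-6, nA = 1e-9)
  )
  if (!unit %in% names(tab)) {
    stop("Unknown ", kind, " unit: ", unit, call. = FALSE)
  }
  unname(tab[unit])
}

#' Construct a transfer curve
#'
#' A gate sweep of a liquid-gated graphene FET: drain-source current `i_ds`
#' (A) on a strictly increasing gate-voltage grid `v_gs` (V). The ambipolar
#' V shape carries the Dirac point at its minimum.
#'
#' @param v_gs Gate voltages, V, strictly increasing, length >= 5.
#' @param i_ds Drain currents, A, finite and positive.
#' @param v_ds Drain-source bias, V (metadata).
#' @param label Free-text condition label.
#' @return A tibble of class `transfer_curve` with columns `v_gs`, `i_ds`.
#' @export
transfer_curve <- function(v_gs, i_ds, v_ds = NA_real_, label = "") {
  if (length(v_gs) < 5) stop("A transfer curve needs >= 5 points.", call. = FALSE)
  if (length(v_gs) != length(i_ds)) stop("v_gs and i_ds lengths differ.", call. = FALSE)
  if (any(diff(v_gs) <= 0)) {
    stop("v_gs must be strictly increasing.", call. = FALSE)
  }
  if (!all(is.finite(i_ds)) || any(i_ds <= 0)) {
    stop("i_ds must be finite and positive.", call. = FALSE)
  }
  structure(
    tibble::tibble(v_gs = as.numeric(v_gs), i_ds = as.numeric(i_ds)),
    v_ds = v_ds, label = label,
    class = c("transfer_curve", class(tibble::tibble()))
  )
}

#' Construct a dose-response table
#'
#' Dirac-point shifts (mV) versus target concentration (mol/L). Zero
#' concentration rows are negative controls. The table is flagged
#' fitting-eligible only when it holds at least two distinct positive
#' concentrations (three are required by [fit_sips()]).
#'
#' @param concentration mol/L, >= 0.
#' @param shift_mv Dirac shift in mV (sign as measured; fitting uses |shift|).
#' @param replicate_id Integer replicate index.
#' @param is_negative_control Logical; defaults to `concentration == 0`.
#' @return A tibble of class `dose_response`.
#' @export
dose_response <- function(concentration, shift_mv,
                          replicate_id = 1L,
                          is_negative_control = concentration == 0) {
  if (any(concentration < 0)) stop("Concentrations must be >= 0.", call. = FALSE)
  out <- tibble::tibble(
    concentration = as.numeric(concentration),
    shift_mv = as.numeric(shift_mv),
    replicate_id = as.integer(replicate_id),
    is_negative_control = as.logical(is_negative_control)
  )
  eligible <- length(unique(out$concentration[out$concentration > 0])) >= 2
  structure(out,
    fit_eligible = eligible,
    class = c("dose_response", class(tibble::tibble()))
  )
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ";"
}

#' Read a transfer curve or dose-response table from delimited text
#'
#' CSV/TSV autodetected from the header line. Declared column units are
#' converted so internal storage is always V, A, mol/L and mV.
#'
#' @param path File path.
#' @param schema `"transfer_curve"` or `"dose_response"`.
#' @param units Named list of column units, e.g.
#'   `list(v_gs = "V", i_ds = "A")` or `list(concentration = "aM",
#'   shift = "mV")`.
#' @param label Condition label (transfer curves).
#' @return A [transfer_curve()] or [dose_response()].
#' @export
read_table <- function(path, schema = c("transfer_curve", "dose_response"),
                       units = list(), label = "") {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  df <- readr::read_delim(path,
    delim = detect_delim(path), show_col_types = FALSE,
    progress = FALSE
  )
  if (schema == "transfer_curve") {
    need <- c("v_gs", "i_ds")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("Missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    v_mult <- unit_multiplier(units$v_gs %||% "V", "voltage")
    i_mult <- unit_multiplier(units$i_ds %||% "A", "current")
    v_ds <- if ("v_ds" %in% names(df)) df$v_ds[1] else NA_real_
    transfer_curve(df$v_gs * v_mult, df$i_ds * i_mult, v_ds = v_ds, label = label)
  } else {
    miss <- setdiff(c("concentration", "shift"), names(df))
    if (length(miss)) {
      stop("Missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    c_mult <- unit_multiplier(units$concentration %||% "M", "concentration")
    s_mult <- unit_multiplier(units$shift %||% "mV", "voltage") / 1e-3
    dose_response(
      concentration = df$concentration * c_mult,
      shift_mv = df$shift * s_mult,
      replicate_id = if ("replicate_id" %in% names(df)) df$replicate_id else 1L,
      is_negative_control = if ("is_negative_control" %in% names(df)) {
        as.logical(df$is_negative_control)
      } else {
        df$concentration == 0
      }
    )
  }
}

#' Write a transfer curve or dose-response table as CSV
#'
#' Values are written at full double precision so read/write round-trips are
#' exact to well past 9 significant digits.
#'
#' @param x A [transfer_curve()] or [dose_response()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- tibble::as_tibble(x)
  if (inherits(x, "dose_response")) {
    names(df)[names(df) == "shift_mv"] <- "shift"
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a nested key-value configuration file (JSON)
#'
#' @param path Path to a JSON config file.
#' @return A nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
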
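# Interchange-format readers and writers. Every writer emits a first-line
# header "# chirassign <schema> v<major>"; readers check the schema name and
# major version and report row diagnostics in errors.

.SCHEMA_VERSION <- 1L

.write_with_header <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chirassign %s v%d", schema, .SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_with_header <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first,
                  regexec("^# chirassign ([a-z_]+) v([0-9]+)", first))[[1]]
  if (length(m)) {
    if (m[2] != schema)
      stop(path, ": schema is ", sQuote(m[2]), ", expected ", sQuote(schema))
    if (as.integer(m[3]) > .SCHEMA_VERSION)
      stop(path, ": schema major version ", m[3], " is newer than supported ",
           .SCHEMA_VERSION)
    skip <- 1L
  } else {
    skip <- 0L  # headerless files are accepted as current-version
  }
  utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
}

#' Read and write conformer tables
#'
#' A conformer table holds one ensemble: columns `id`, `rel_energy_kjmol`,
#' then zero or more wide shielding columns named `sigma_<label>` (dashes in
#' nucleus labels are preserved, e.g. `sigma_C-17`).
#'
#' @param path File path.
#' @param stereo_label Stereodescriptor to attach to the ensemble.
#' @param temperature Ensemble temperature in K.
#' @return [read_conformer_table()] returns an [ensemble()];
#'   `write_conformer_table` returns the path invisibly.
#' @export
read_conformer_table <- function(path, stereo_label = basename(path),
                                 temperature = 298.15) {
  df <- .read_with_header(path, "conformer_table")
  # read.csv mangles "sigma_C-17" to "sigma_C.17"; undo for label fidelity
  names(df) <- sub("^sigma_", "sigma|", names(df))
  names(df) <- ifelse(startsWith(names(df), "sigma|"),
                      gsub(".", "-", names(df), fixed = TRUE), names(df))
  .require_cols(df, c("id", "rel_energy_kjmol"), path)
  sigma_cols <- grep("^sigma\\|", names(df), value = TRUE)
  labels <- sub("^sigma\\|", "", sigma_cols)
  confs <- lapply(seq_len(nrow(df)), function(i) {
    sh <- if (length(sigma_cols)) {
      v <- as.numeric(df[i, sigma_cols])
      if (anyNA(v)) stop(path, ": row ", i, ": non-numeric shielding")
      stats::setNames(v, labels)
    } else NULL
    conformer_record(df$id[i], df$rel_energy_kjmol[i], shieldings = sh)
  })
  ensemble(stereo_label, confs, temperature)
}

#' @rdname read_conformer_table
#' @param ens An [ensemble()].
#' @export
write_conformer_table <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  df <- data.frame(id = vapply(ens$conformers, `[[`, character(1), "id"),
                   rel_energy_kjmol = .rel_energies(ens))
  sh <- ens$conformers[[1]]$shieldings
  if (!is.null(sh)) {
    for (lab in names(sh))
      df[[paste0("sigma_", lab)]] <-
        vapply(ens$conformers, function(cf) cf$shieldings[[lab]], numeric(1))
  }
  .write_with_header(df, path, "conformer_table")
}

#' Read and write per-conformer transition tables
#'
#' Columns: `conformer_id`, `wavelength_nm` (or `energy_ev` / `energy_cm1`),
#' `R_vel` (1e-40 cgs), optional `f_osc`.
#'
#' @param path File path.
#' @return `read_transitions` returns a named list (by conformer id) of
#'   transition data frames.
#' @export
read_transitions <- function(path) {
  df <- .read_with_header(path, "transitions")
  .require_cols(df, "conformer_id", path)
  if (!any(c("wavelength_nm", "energy_ev", "energy_cm1") %in% names(df)))
    stop(path, ": need a wavelength_nm, energy_ev or energy_cm1 column")
  .require_cols(df, "R_vel", path)
  split(df[setdiff(names(df), "conformer_id")], df$conformer_id)
}

#' @rdname read_transitions
#' @param transitions Named list of transition data frames (names are
#'   conformer ids), or an [ensemble()] carrying transitions.
#' @export
write_transitions <- function(transitions, path) {
  if (inherits(transitions, "ensemble")) {
    ens <- transitions
    transitions <- stats::setNames(
      lapply(ens$conformers, `[[`, "transitions"),
      vapply(ens$conformers, `[[`, character(1), "id"))
  }
  stopifnot(is.list(transitions), !is.null(names(transitions)))
  df <- do.call(rbind, lapply(names(transitions), function(id) {
    cbind(conformer_id = id, as.data.frame(transitions[[id]]))
  }))
  .write_with_header(df, path, "transitions")
}

#' Read and write ECD spectra
#'
#' Two-column text: `wavelength_nm`, `delta_epsilon`.
#'
#' @param path File path.
#' @return `read_spectrum` returns an [ecd_spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- .read_with_header(path, "spectrum")
  .require_cols(df, c("wavelength_nm", "delta_epsilon"), path)
  ecd_spectrum(df$wavelength_nm, df$delta_epsilon)
}

#' @rdname read_spectrum
#' @param s An [ecd_spectrum()].
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "ecd_spectrum"))
  .write_with_header(data.frame(wavelength_nm = s$wavelength_nm,
                                delta_epsilon = s$delta_epsilon),
                     path, "spectrum")
}

#' Read and write shift tables
#'
#' Columns: `label`, `nucleus`, `delta_ppm`, plus optional metadata columns
#' carried verbatim.
#'
#' @param path File path.
#' @return `read_shift_table` returns a [shift_table()].
#' @export
read_shift_table <- function(path) {
  df <- .read_with_header(path, "shift_table")
  .require_cols(df, c("label", "delta_ppm"), path)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$delta_ppm))))
  if (length(bad))
    stop(path, ": row ", bad[1], ": non-numeric delta_ppm ",
         sQuote(df$delta_ppm[bad[1]]))
  extra <- setdiff(names(df), c("label", "nucleus", "delta_ppm"))
  do.call(shift_table,
          c(list(label = df$label, delta_ppm = as.numeric(df$delta_ppm),
                 nucleus = if ("nucleus" %in% names(df)) df$nucleus else NULL),
            df[extra]))
}

#' @rdname read_shift_table
#' @param tab A [shift_table()].
#' @export
write_shift_table <- function(tab, path) {
  stopifnot(inherits(tab, "shift_table"))
  .write_with_header(as.data.frame(tab), path, "shift_table")
}

#' Load the packaged experimental shift table of a compound
#'
#' The packaged tables transcribe the printed DMSO-d6 1H/13C shift data of
#' the three aplospojaveedins. Rows without a printed shift (exchangeable NH
#' positions with no observed signal) are dropped.
#'
#' @param compound Compound number 1, 2 or 3.
#' @return A [shift_table()] with extra columns `position`, `type`,
#'   `multiplicity`.
#' @export
load_compound_shifts <- function(compound = 1) {
  stopifnot(compound %in% 1:3)
  path <- system.file("extdata",
                      sprintf("table1_compound%d.csv", compound),
                      package = "chirassign", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[is.finite(suppressWarnings(as.numeric(df$delta_ppm))), ]
  shift_table(label = df$label, delta_ppm = as.numeric(df$delta_ppm),
              nucleus = df$nucleus, position = df$position,
              type = df$type, multiplicity = df$multiplicity)
}

#' Read and write docking pose sets
#'
#' Poses are exchanged as concatenated XYZ (one block per pose, with
#' `id=<id> score=<x>` in the comment line) or multi-model PDB
#' (`MODEL`/`ENDMDL`, `ATOM`/`HETATM` records; the score is taken from a
#' `REMARK score` line inside the model when present).
#'
#' @param path File path; format detected from content.
#' @return `read_poses` returns a [pose_set()].
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (any(grepl("^MODEL", lines))) .read_poses_pdb(lines, path)
  else .read_poses_xyz(lines, path)
}

.read_poses_xyz <- function(lines, path) {
  i <- 1L; n_lines <- length(lines)
  coords <- list(); ids <- character(); scores <- numeric(); atoms <- NULL
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop(path, ": line ", i, ": expected an atom count, got ",
           sQuote(lines[i]))
    if (i + 1L + n > n_lines)
      stop(path, ": line ", i, ": truncated XYZ block (needs ", n, " atoms)")
    comment <- lines[i + 1L]
    id <- sub(".*id=([^ ]+).*", "\\1", comment)
    if (id == comment) id <- paste0("pose_", length(coords) + 1L)
    score <- suppressWarnings(
      as.numeric(sub(".*score=([-0-9.eE+]+).*", "\\1", comment)))
    if (is.na(score)) score <- 0
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    if (any(vapply(parts, length, integer(1)) < 4L))
      stop(path, ": line ", i + 2L, ": XYZ atom lines need symbol x y z")
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(m)) stop(path, ": non-numeric coordinate near line ", i + 2L)
    if (is.null(atoms)) atoms <- vapply(parts, `[[`, character(1), 1L)
    coords[[length(coords) + 1L]] <- m
    ids <- c(ids, id); scores <- c(scores, score)
    i <- i + 2L + n
  }
  if (!length(coords)) stop(path, ": no XYZ blocks found")
  pose_set(coords, ids, scores, atoms)
}

.read_poses_pdb <- function(lines, path) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) != length(ends))
    stop(path, ": unbalanced MODEL/ENDMDL records")
  coords <- list(); ids <- character(); scores <- numeric(); atoms <- NULL
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    at <- grep("^(ATOM|HETATM)", block, value = TRUE)
    if (!length(at)) stop(path, ": model ", k, " has no atom records")
    x <- as.numeric(substr(at, 31, 38))
    y <- as.numeric(substr(at, 39, 46))
    z <- as.numeric(substr(at, 47, 54))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop(path, ": model ", k, ": malformed coordinate field")
    name <- trimws(substr(at, 13, 16))
    keep <- !grepl("^[0-9]*H", name)  # drop hydrogens
    if (is.null(atoms)) atoms <- name[keep]
    coords[[k]] <- cbind(x, y, z)[keep, , drop = FALSE]
    ids <- c(ids, paste0("model_", trimws(sub("^MODEL", "", lines[starts[k]]))))
    sc <- grep("^REMARK +score", block, value = TRUE)
    scores <- c(scores, if (length(sc))
      as.numeric(sub(".*score[ =]+([-0-9.eE+]+).*", "\\1", sc[1])) else 0)
  }
  pose_set(coords, ids, scores, atoms)
}

#' @rdname read_poses
#' @param poses A [pose_set()].
#' @export
write_poses_xyz <- function(poses, path) {
  stopifnot(inherits(poses, "pose_set"))
  atoms <- if (is.null(poses$atoms)) rep("C", nrow(poses$coords[[1]]))
           else poses$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(poses$coords)) {
    m <- poses$coords[[i]]
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("id=%s score=%.6g", poses$ids[i], poses$scores[i]),
               con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       atoms, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a pocket definition
#'
#' Accepts a one-line centroid spec `"x,y,z,r"` or a coordinate file (XYZ
#' block or PDB atom records) whose atoms become the pocket reference set.
#'
#' @param path File path.
#' @return A [pocket_definition()].
#' @export
read_pocket <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 1L && grepl("^[-0-9.eE+]+(,[-0-9.eE+]+){3}$",
                                   gsub(" ", "", lines[1]))) {
    v <- as.numeric(strsplit(gsub(" ", "", lines[1]), ",")[[1]])
    return(pocket_definition(centroid = v[1:3], radius = v[4]))
  }
  ps <- read_poses(path)
  pocket_definition(coords = do.call(rbind, ps$coords))
}

#' Extract shieldings and transitions from quantum-chemistry text logs
#'
#' Convenience scrapers for the common text-log layout of GIAO NMR and
#' excited-state TDDFT outputs. `extract_shieldings_from_log` collects
#' per-nucleus lines of the form
#' `"  5  C    Isotropic =   45.1234  Anisotropy =  ..."` into a named
#' shielding vector (labels `<Element>-<index>`).
#' `extract_transitions_from_log` collects `"Excited State  n: ... <x> eV
#' <y> nm f=<z>"` blocks together with the velocity rotational-strength
#' table (rows `state  X  Y  Z  R(velocity)`).
#'
#' @param path Path to the log file.
#' @return A named numeric vector of shieldings, or a data frame with
#'   columns `wavelength_nm`, `energy_ev`, `f_osc`, `R_vel`.
#' @export
extract_shieldings_from_log <- function(path) {
  lines <- readLines(path)
  hits <- grep("Isotropic\\s*=", lines, value = TRUE)
  if (!length(hits))
    stop(path, ": no 'Isotropic =' shielding lines found")
  m <- regmatches(hits, regexec(
    "^\\s*([0-9]+)\\s+([A-Za-z]+)\\s+Isotropic\\s*=\\s*([-0-9.]+)", hits))
  ok <- vapply(m, length, integer(1)) == 4L
  if (!any(ok)) stop(path, ": shielding lines present but unparseable")
  m <- m[ok]
  stats::setNames(vapply(m, function(g) as.numeric(g[4]), numeric(1)),
                  vapply(m, function(g) paste0(g[3], "-", g[2]), character(1)))
}

#' @rdname extract_shieldings_from_log
#' @export
extract_transitions_from_log <- function(path) {
  lines <- readLines(path)
  es <- grep("Excited State", lines, value = TRUE)
  if (!length(es)) stop(path, ": no 'Excited State' blocks found")
  ev <- as.numeric(sub(".*?([0-9.]+)\\s*eV.*", "\\1", es))
  nm <- as.numeric(sub(".*?([0-9.]+)\\s*nm.*", "\\1", es))
  f  <- suppressWarnings(as.numeric(sub(".*f\\s*=\\s*([-0-9.]+).*", "\\1", es)))
  # velocity rotational strengths: lines "  <state>  <X> <Y> <Z>  <R>"
  hdr <- grep("R\\(velocity\\)", lines)
  R <- rep(NA_real_, length(es))
  if (length(hdr)) {
    i <- hdr[1] + 1L
    while (i <= length(lines)) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(parts) < 5L ||
          is.na(suppressWarnings(as.integer(parts[1])))) break
      state <- as.integer(parts[1])
      if (state >= 1L && state <= length(R))
        R[state] <- as.numeric(parts[5])
      i <- i + 1L
    }
  }
  if (all(is.na(R)))
    stop(path, ": no velocity rotational-strength table found")
  data.frame(wavelength_nm = nm, energy_ev = ev, f_osc = f, R_vel = R)
}
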
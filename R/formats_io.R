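#' Read a PDB file into a structure
#'
#' Thin wrapper around [bio3d::read.pdb()]. All ATOM and HETATM records are
#' kept, including waters and heme groups. When the element column is
#' absent or blank the element is inferred from the atom name.
#'
#' @param path PDB file path
#' @return a `trxss_structure`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  if (any(blank)) elem[blank] <- infer_element(at$elety[blank])
  structure_from_atoms(data.frame(
    element = toupper(trimws(elem)),
    elety = trimws(at$elety),
    resid = trimws(at$resid),
    resno = at$resno,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    type = at$type,
    stringsAsFactors = FALSE))
}

# first alphabetic character of the atom name, two-letter elements handled
infer_element <- function(elety) {
  elety <- toupper(trimws(elety))
  two <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "CA")
  out <- substr(gsub("[^A-Z]", "", elety), 1, 1)
  hit <- substr(gsub("[^A-Z]", "", elety), 1, 2) %in% two &
    nchar(gsub("[^A-Z]", "", elety)) >= 2 & !grepl("^CA$|^CB$|^CD", elety)
  out[hit] <- substr(gsub("[^A-Z]", "", elety[hit]), 1, 2)
  out
}

#' Write a structure to a PDB file
#'
#' Fixed-width wwPDB v3.3 records via [bio3d::write.pdb()]; explicit waters
#' are emitted as HETATM records with residue name HOH. Coordinates keep
#' the PDB's three-decimal precision, so a read/write round trip preserves
#' them to 1e-3 Angstrom.
#'
#' @param structure a `trxss_structure`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_pdb <- function(structure, path) {
  at <- as.data.frame(structure)
  type <- ifelse(at$is_water | at$resid %in% c("HOH", "HEM") |
                   at$type == "HETATM", "HETATM", "ATOM")
  resid <- at$resid
  resid[at$is_water] <- "HOH"
  xyz <- as.vector(t(coords(structure)))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz, type = type,
                     resno = at$resno, resid = resid, chain = at$chain,
                     elety = at$elety, elesy = at$element,
                     eleno = seq_len(nrow(at)))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("could not write PDB to ", path)
  invisible(path)
}

#' Parse a time-delay string to seconds
#'
#' Accepts a numeric value with a case-insensitive unit suffix among
#' ps, ns, us (or the Greek mu variant), ms, s; a bare number is taken as
#' seconds. `"100ps"`, `"0.1ns"` and `"1e-10s"` all map to 1e-10.
#'
#' @param x character vector of delay strings
#' @return numeric vector of delays in seconds
#' @export
parse_delay <- function(x) {
  x <- trimws(tolower(as.character(x)))
  x <- gsub("μs$|µs$", "us", x)
  unit <- rep(1, length(x))
  num <- x
  # "s" is a suffix of every other unit, so specific units are stripped first
  tab <- c(ps = 1e-12, ns = 1e-9, us = 1e-6, ms = 1e-3, s = 1)
  for (nm in names(tab)) {
    hit <- grepl(paste0(nm, "$"), num)
    unit[hit] <- tab[[nm]]
    num[hit] <- sub(paste0(nm, "$"), "", num[hit])
  }
  val <- suppressWarnings(as.numeric(num))
  if (any(is.na(val))) stop("unparseable delay value(s): ",
                            paste(x[is.na(val)], collapse = ", "))
  val * unit
}

format_delay <- function(sec) sprintf("%.6gs", sec)

#' Construct a scattering curve
#'
#' @param q momentum transfer grid in 1/Angstrom, strictly increasing, > 0
#' @param intensity intensities (arbitrary units), same length as `q`
#' @param sigma optional per-point uncertainties, > 0
#' @return object of class `trxss_curve`: a data frame `q`, `intensity`
#'   (and `sigma` when supplied)
#' @export
scattering_curve <- function(q, intensity, sigma = NULL) {
  stopifnot(length(q) == length(intensity))
  if (any(q <= 0)) stop("q values must be positive")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  cur <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    if (any(sigma <= 0)) stop("sigma must be positive where present")
    cur$sigma <- sigma
  }
  class(cur) <- c("trxss_curve", "data.frame")
  cur
}

#' Construct a difference matrix ΔS(q, Δt)
#'
#' @param q q grid (1/Angstrom)
#' @param delays time delays in seconds, strictly increasing
#' @param values matrix of dimension `length(q)` x `length(delays)`
#' @param sigma per-point uncertainty: scalar, or matrix like `values`
#' @return object of class `trxss_diffmat` (list with fields `q`,
#'   `delays`, `values`, `sigma`)
#' @export
difference_matrix <- function(q, delays, values, sigma = NULL) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(q), length(delays)))) {
    stop("values must be length(q) x length(delays)")
  }
  if (is.unsorted(delays, strictly = TRUE)) stop("delays must be strictly increasing")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  out <- list(q = q, delays = delays, values = values, sigma = sigma)
  class(out) <- "trxss_diffmat"
  out
}

#' @export
print.trxss_diffmat <- function(x, ...) {
  cat(sprintf("<trxss_diffmat> %d q-points (%.3g-%.3g 1/A) x %d delays (%.3g-%.3g s)\n",
              length(x$q), min(x$q), max(x$q), length(x$delays),
              min(x$delays), max(x$delays)))
  invisible(x)
}

#' Read a difference-curve matrix from a delimited text table
#'
#' Expected layout: one header row `q <delay1> <delay2> ...` where delays
#' carry units parsed by [parse_delay()]; first column is the q grid.
#' Whitespace- or comma-delimited. Columns are re-ordered so delays come
#' out ascending, and rows outside the q window are dropped.
#'
#' @param path file path
#' @param qlim length-2 q window in 1/Angstrom (default `c(0.15, 1)`);
#'   `NULL` keeps the full grid
#' @return a `trxss_diffmat`
#' @export
read_difference_matrix <- function(path, qlim = c(0.15, 1.0)) {
  ln <- readLines(path)
  ln <- ln[trimws(ln) != ""]
  if (length(ln) < 2L) stop("matrix table needs a header and at least one row")
  split_row <- function(s) strsplit(trimws(s), "[,[:space:]]+")[[1]]
  hdr <- split_row(ln[1])
  delays <- parse_delay(hdr[-1])
  rows <- lapply(ln[-1], split_row)
  nc <- lengths(rows)
  if (any(nc != length(hdr))) {
    stop("inconsistent row length at data line ", which(nc != length(hdr))[1])
  }
  m <- do.call(rbind, lapply(rows, as.numeric))
  q <- m[, 1]
  if (is.unsorted(q, strictly = TRUE)) stop("q column must be strictly increasing")
  vals <- m[, -1, drop = FALSE]
  ord <- order(delays)
  delays <- delays[ord]
  vals <- vals[, ord, drop = FALSE]
  if (!is.null(qlim)) {
    keep <- q >= qlim[1] & q <= qlim[2]
    q <- q[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  difference_matrix(q, delays, vals)
}

#' Write a difference matrix as a text table
#'
#' Inverse of [read_difference_matrix()]; delays are written in seconds
#' with an `s` suffix at full double precision.
#'
#' @param mat a `trxss_diffmat`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_difference_matrix <- function(mat, path) {
  hdr <- paste(c("q", sprintf("%.17gs", mat$delays)), collapse = " ")
  body <- apply(cbind(mat$q, mat$values), 1,
                function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read/write a single scattering curve table
#'
#' Columns `q intensity [sigma]`, one header row.
#'
#' @param path file path
#' @return a `trxss_curve`
#' @export
read_curve <- function(path) {
  tb <- read.table(path, header = TRUE)
  scattering_curve(tb$q, tb$intensity,
                   sigma = if ("sigma" %in% names(tb)) tb$sigma else NULL)
}

#' @rdname read_curve
#' @param curve a `trxss_curve`
#' @export
write_curve <- function(curve, path) {
  write.table(format(as.data.frame(curve), digits = 17), path,
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis summary as structured, re-parseable text
#'
#' `record` is a named list; scalar entries become `key: value` lines and
#' data-frame entries become named TSV blocks delimited by
#' `[table <name>]` / `[end]`. [read_results()] reconstructs the list.
#'
#' @param record named list of scalars/vectors and data frames
#' @param path output path
#' @return invisibly, `path`
#' @export
write_results <- function(record, path) {
  stopifnot(is.list(record), !is.null(names(record)))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(record)) {
    v <- record[[nm]]
    if (is.data.frame(v)) {
      writeLines(sprintf("[table %s]", nm), con)
      writeLines(paste(names(v), collapse = "\t"), con)
      if (nrow(v) > 0) {
        writeLines(apply(v, 1, function(r) paste(format(r, digits = 17,
                                                        trim = TRUE),
                                                 collapse = "\t")), con)
      }
      writeLines("[end]", con)
    } else {
      writeLines(sprintf("%s: %s", nm,
                         paste(format(v, digits = 17, trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  ln <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(ln)) {
    l <- ln[i]
    if (grepl("^\\[table ", l)) {
      nm <- sub("^\\[table (.*)\\]$", "\\1", l)
      hdr <- strsplit(ln[i + 1L], "\t")[[1]]
      j <- i + 2L
      rows <- character(0)
      while (ln[j] != "[end]") {
        rows <- c(rows, ln[j]); j <- j + 1L
      }
      if (length(rows) > 0) {
        df <- as.data.frame(do.call(rbind, strsplit(rows, "\t")),
                            stringsAsFactors = FALSE)
        names(df) <- hdr
        for (cc in names(df)) {
          num <- suppressWarnings(as.numeric(df[[cc]]))
          if (!any(is.na(num))) df[[cc]] <- num
        }
      } else {
        df <- as.data.frame(setNames(rep(list(numeric(0)), length(hdr)), hdr))
      }
      out[[nm]] <- df
      i <- j + 1L
    } else if (grepl(":", l, fixed = TRUE)) {
      nm <- sub(":.*$", "", l)
      val <- trimws(sub("^[^:]*:", "", l))
      parts <- strsplit(val, " +")[[1]]
      num <- suppressWarnings(as.numeric(parts))
      out[[nm]] <- if (!any(is.na(num))) num else val
      i <- i + 1L
    } else i <- i + 1L
  }
  out
}

#' Read a YAML configuration file
#'
#' Settings for the kinetic scheme (names as in [kinetic_params()]) and
#' for refinement; values found in the file override `defaults`.
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @param defaults named list of fallback settings
#' @return merged named list
#' @export
read_config <- function(path = NULL, defaults = list()) {
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  utils::modifyList(defaults, cfg)
}
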
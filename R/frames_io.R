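## Coordinate-frame input: GRO files (possibly multi-frame) or a plain CSV
## frame table with columns frame, resname, atomname, x, y, z, mass.

## default masses (g/mol) by leading element letter of the atom name
element_mass <- function(atomname) {
  first <- toupper(substr(gsub("^[0-9]+", "", atomname), 1, 1))
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
         S = 32.06)
  out <- unname(m[first])
  out[is.na(out)] <- 12.011
  out
}

#' Read coordinate frames from a GRO file
#'
#' Fixed-width GROMACS coordinate format; multiple concatenated frames are
#' supported. Masses are assigned from the leading element letter of the
#' atom name unless supplied.
#'
#' @param path Path to a .gro file.
#' @param masses Optional named vector, atom name -> mass (g/mol).
#' @return Frame table: data.frame(frame, resname, atomname, x, y, z, mass)
#'   with attribute `box` (last frame's box vector, nm).
#' @export
read_gro_frames <- function(path, masses = NULL) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frame_no <- 0L
  out <- list()
  box <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) stop("gro parse error: bad atom count at line ", i + 1)
    frame_no <- frame_no + 1L
    rows <- lines[(i + 2L):(i + 1L + natoms)]
    resname <- trimws(substr(rows, 6, 10))
    atomname <- trimws(substr(rows, 11, 15))
    x <- as.numeric(substr(rows, 21, 28))
    y <- as.numeric(substr(rows, 29, 36))
    z <- as.numeric(substr(rows, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      stop("gro parse error: non-numeric coordinates in frame ", frame_no)
    }
    mass <- if (!is.null(masses)) {
      mm <- unname(masses[atomname])
      mm[is.na(mm)] <- element_mass(atomname[is.na(mm)])
      mm
    } else element_mass(atomname)
    out[[frame_no]] <- data.frame(
      frame = frame_no, resname = resname, atomname = atomname,
      x = x, y = y, z = z, mass = mass, stringsAsFactors = FALSE)
    box <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    i <- i + 3L + natoms
  }
  if (frame_no == 0L) stop("gro parse error: empty file")
  res <- do.call(rbind, out)
  attr(res, "box") <- box
  res
}

#' Read a CSV frame table
#'
#' @param path CSV with columns frame, resname, atomname, x, y, z, mass.
#' @return Frame table data.frame.
#' @export
read_frame_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "resname", "atomname", "x", "y", "z", "mass")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("frame table missing columns: ", paste(miss, collapse = ", "))
  }
  df
}

#' Read frames from GRO or CSV, by extension
#'
#' @param path Path ending in .gro or .csv.
#' @param ... Passed to the format reader.
#' @return Frame table.
#' @export
read_frames <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = read_gro_frames(path, ...),
         csv = read_frame_table(path),
         stop("unsupported frame format: .", ext))
}
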
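## Plain-text interchange: photon CSV, ground-truth TSV, GRO-like and XYZ
## frames, umbrella-window YAML metadata.

#' Write photon streams to a flat CSV
#'
#' Columns: molecule_id, macrotime_s, nanotime_ns, channel.
#'
#' @param streams list of [PhotonStream-class] objects (molecule ids taken
#'   from metadata, else list position).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhotonCsv <- function(streams, path) {
  rows <- lapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    id <- if (!is.null(s@meta$molecule_id)) s@meta$molecule_id else i
    if (!length(s)) return(NULL)
    data.frame(molecule_id = id, macrotime_s = s@macrotime,
               nanotime_ns = s@nanotime, channel = s@channel)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(molecule_id = integer(), macrotime_s = numeric(),
                     nanotime_ns = numeric(), channel = character())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read photon streams from a flat CSV
#'
#' @param path CSV written by [writePhotonCsv()].
#' @param duration acquisition duration to stamp on each stream (default:
#'   per-molecule max macrotime).
#' @return Named list of [PhotonStream-class] objects, one per molecule.
#' @export
readPhotonCsv <- function(path, duration = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  by <- split(df, df$molecule_id)
  lapply(by, function(d) {
    d <- d[order(d$macrotime_s), ]
    PhotonStream(macrotime = d$macrotime_s, nanotime = d$nanotime_ns,
                 channel = d$channel, duration = duration,
                 meta = list(molecule_id = d$molecule_id[1]))
  })
}

#' Write a coarse-grained frame as GRO-like text
#'
#' Fixed-width GRO layout (residue id+name, bead name, index, x y z in nm)
#' with the box on the last line. Lipid beads get residue name `LIP`,
#' protein beads `PRO`, solvent `SOL`.
#'
#' @param frame a [TrajectoryFrame-class] (coordinates in Angstrom;
#'   written in nm per the format convention).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGro <- function(frame, path) {
  n <- nrow(frame@coords)
  resname <- c(lipid = "LIP", protein = "PRO", solvent = "SOL")[frame@kind]
  resid <- ifelse(is.na(frame@residueId), 0L, frame@residueId)
  lines <- c("memfret coarse-grained frame", sprintf("%5d", n))
  nm <- frame@coords / 10
  lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            resid %% 100000L, resname, "BB", seq_len(n) %% 100000L,
                            nm[, 1], nm[, 2], nm[, 3]))
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", frame@box[1] / 10,
                            frame@box[2] / 10, frame@box[3] / 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO-like frame
#'
#' @param path file written by [writeGro()] (or equivalent fixed-width GRO
#'   text with LIP/PRO/SOL residue names).
#' @param periodic periodic flag for the resulting frame.
#' @return A [TrajectoryFrame-class] (coordinates converted to Angstrom).
#' @export
readGro <- function(path, periodic = TRUE) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  atom <- lines[3:(2 + n)]
  resid <- as.integer(substr(atom, 1, 5))
  resname <- trimws(substr(atom, 6, 10))
  xyz <- cbind(as.numeric(substr(atom, 21, 28)),
               as.numeric(substr(atom, 29, 36)),
               as.numeric(substr(atom, 37, 44))) * 10
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3] * 10
  kind <- c(LIP = "lipid", PRO = "protein", SOL = "solvent")[resname]
  TrajectoryFrame(coords = xyz, kind = unname(kind),
                  residueId = ifelse(kind == "protein", resid, NA_integer_),
                  box = box, periodic = periodic)
}

#' Write a frame as labeled XYZ text
#'
#' @param frame a [TrajectoryFrame-class]; coordinates stay in Angstrom.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeXyz <- function(frame, path) {
  n <- nrow(frame@coords)
  resid <- ifelse(is.na(frame@residueId), 0L, frame@residueId)
  lines <- c(sprintf("%d", n),
             sprintf("box %.4f %.4f %.4f", frame@box[1], frame@box[2],
                     frame@box[3]),
             sprintf("%s %d %.4f %.4f %.4f", frame@kind, resid,
                     frame@coords[, 1], frame@coords[, 2], frame@coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled XYZ frame written by [writeXyz()]
#'
#' @param path input file.
#' @param periodic periodic flag.
#' @return A [TrajectoryFrame-class].
#' @export
readXyz <- function(path, periodic = TRUE) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  box <- as.numeric(strsplit(lines[2], "\\s+")[[1]][2:4])
  parts <- strsplit(lines[3:(2 + n)], "\\s+")
  kind <- vapply(parts, `[[`, character(1), 1)
  resid <- as.integer(vapply(parts, `[[`, character(1), 2))
  xyz <- t(vapply(parts, function(p) as.numeric(p[3:5]), numeric(3)))
  TrajectoryFrame(coords = xyz, kind = kind,
                  residueId = ifelse(kind == "protein", resid, NA_integer_),
                  box = box, periodic = periodic)
}

#' Read umbrella-window metadata and series from YAML
#'
#' The YAML file holds a list of windows, each with `center`, `spring_k` and
#' either an inline `series` or a `series_file` (one value per line,
#' relative to the YAML's directory).
#'
#' @param path YAML file.
#' @return List of [UmbrellaWindow-class] objects.
#' @export
readUmbrellaYaml <- function(path) {
  meta <- yaml::read_yaml(path)
  base <- dirname(path)
  lapply(meta$windows, function(w) {
    cv <- if (!is.null(w[["series"]])) as.numeric(w[["series"]])
          else as.numeric(readLines(file.path(base, w[["series_file"]])))
    UmbrellaWindow(center = w[["center"]], springK = w[["spring_k"]], cv = cv)
  })
}
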
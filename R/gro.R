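# Fixed-column GRO coordinate files (nm; velocities in nm/ps, optional).

.RESNAME <- c(polarizable_water = "PW", standard_water = "W", butane = "BUT",
              octane = "OCT", hexadecane = "HD", cation = "ION", anion = "ION")
.ATOMNAME <- c("POL-W" = "W", "POL-WP" = "WP", "POL-WM" = "WM", "P4" = "W",
               "C1" = "C", "Qd" = "NA", "Qa" = "CL")

#' Write a system to a GRO file
#'
#' Fixed-column format: positions with 3 decimals (nm), velocities with 4
#' decimals (nm/ps). Positions are wrapped into the box on output.
#'
#' @param system a \code{cg_system}.
#' @param path output file.
#' @param velocities write the velocity columns (default TRUE).
#' @param title header line.
#' @param append append as an additional frame (multi-frame trajectory GRO).
#' @return \code{path}, invisibly.
#' @export
write_gro <- function(system, path, velocities = TRUE,
                      title = "polwater system", append = FALSE) {
  s <- system$sites
  n <- nrow(s)
  resname <- .RESNAME[s$mol_name]
  resname[is.na(resname)] <- substr(s$mol_name[is.na(resname)], 1, 5)
  atom <- .ATOMNAME[s$type]
  atom[is.na(atom)] <- substr(s$type[is.na(atom)], 1, 5)
  # per-molecule atom numbering for alkanes etc. keeps names unique
  pos <- cbind(s$x %% system$box[1], s$y %% system$box[2], s$z %% system$box[3])
  lines <- character(n + 3)
  lines[1] <- title
  lines[2] <- sprintf("%5d", n)
  resid <- s$mol_id %% 100000L
  atomid <- seq_len(n) %% 100000L
  body <- if (velocities)
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
            resid, resname, atom, atomid, pos[, 1], pos[, 2], pos[, 3],
            s$vx, s$vy, s$vz)
  else
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resid, resname, atom, atomid, pos[, 1], pos[, 2], pos[, 3])
  lines[3:(n + 2)] <- body
  lines[n + 3] <- sprintf("%10.5f%10.5f%10.5f", system$box[1], system$box[2],
                          system$box[3])
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

.parse_gro_frame <- function(lines, offset) {
  title <- lines[offset]
  n <- suppressWarnings(as.integer(trimws(lines[offset + 1])))
  if (is.na(n))
    stop("parse error at line ", offset + 1, ": invalid atom count",
         call. = FALSE)
  if (offset + 1 + n + 1 > length(lines))
    stop("parse error at line ", offset + 1,
         ": atom count exceeds file length", call. = FALSE)
  body <- lines[(offset + 2):(offset + 1 + n)]
  num <- function(str, from, to) {
    v <- suppressWarnings(as.numeric(substr(str, from, to)))
    v
  }
  x <- num(body, 21, 28); y <- num(body, 29, 36); z <- num(body, 37, 44)
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("parse error at line ", offset + 1 + bad[1],
         ": malformed coordinate fields", call. = FALSE)
  has_vel <- all(nchar(body) >= 68)
  if (has_vel) {
    vx <- num(body, 45, 52); vy <- num(body, 53, 60); vz <- num(body, 61, 68)
    if (anyNA(vx) || anyNA(vy) || anyNA(vz)) {
      has_vel <- FALSE; vx <- vy <- vz <- rep(0, n)
    }
  } else vx <- vy <- vz <- rep(0, n)
  boxline <- strsplit(trimws(lines[offset + n + 2]), "\\s+")[[1]]
  box <- suppressWarnings(as.numeric(boxline[1:3]))
  if (anyNA(box))
    stop("parse error at line ", offset + n + 2, ": malformed box line",
         call. = FALSE)
  list(title = title,
       sites = tibble::tibble(
         resid = as.integer(substr(body, 1, 5)),
         resname = trimws(substr(body, 6, 10)),
         atom = trimws(substr(body, 11, 15)),
         x = x, y = y, z = z, vx = vx, vy = vy, vz = vz),
       box = box, has_velocities = has_vel, lines_used = n + 3)
}

#' Read a GRO coordinate file
#'
#' @param path file to read.
#' @return list of class \code{cg_gro}: \code{sites} tibble (resid, resname,
#'   atom, positions, velocities), \code{box}, \code{has_velocities} flag.
#'   Velocities read as zero when the file has no velocity columns.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("parse error: truncated GRO file", call. = FALSE)
  fr <- .parse_gro_frame(lines, 1)
  structure(fr[c("title", "sites", "box", "has_velocities")],
            class = "cg_gro")
}

#' Read a multi-frame (appended) GRO trajectory
#'
#' @param path trajectory file written frame-by-frame with
#'   \code{write_gro(..., append = TRUE)}.
#' @return list with \code{frames} (list of n x 3 matrices), \code{boxes}
#'   (n_frames x 3), \code{sites} (tibble from the first frame), and
#'   \code{times} parsed from \code{t=} tags in frame titles when present.
#' @export
read_trajectory_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); times <- numeric(); sites <- NULL
  off <- 1
  while (off + 2 <= length(lines)) {
    fr <- .parse_gro_frame(lines, off)
    frames[[length(frames) + 1]] <- as.matrix(fr$sites[, c("x", "y", "z")])
    boxes[[length(boxes) + 1]] <- fr$box
    tm <- regmatches(fr$title, regexpr("t=\\s*[-0-9.eE+]+", fr$title))
    times <- c(times, if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else
      length(frames))
    if (is.null(sites)) sites <- fr$sites
    off <- off + fr$lines_used
  }
  list(frames = frames, boxes = do.call(rbind, boxes), times = times,
       sites = sites)
}

# Rebuild a cg_system from a GRO skeleton using the residue-name conventions
# of this package (PW = 3-site polarizable water, W = P4 water, BUT/OCT/HD =
# alkanes, ION = Qd/Qa by atom name).
.system_from_gro <- function(gro) {
  s <- gro$sites
  mols <- list()
  # split on resid change (GRO resids wrap at 1e5, so use runs)
  runs <- cumsum(c(TRUE, diff(s$resid) != 0))
  for (m in split(seq_len(nrow(s)), runs)) {
    rn <- s$resname[m[1]]
    top <- switch(rn,
      PW = molecule_topology("polarizable_water"),
      W = molecule_topology("standard_water"),
      BUT = molecule_topology("butane"),
      OCT = molecule_topology("octane"),
      HD = molecule_topology("hexadecane"),
      ION = molecule_topology(if (s$atom[m[1]] == "NA") "cation" else "anion"),
      stop("unknown residue name in GRO file: ", rn, call. = FALSE))
    mols[[length(mols) + 1]] <- list(
      top = top, pos = as.matrix(s[m, c("x", "y", "z")]),
      vel = as.matrix(s[m, c("vx", "vy", "vz")]))
  }
  sys <- .assemble_system(mols, box = gro$box)
  vel <- do.call(rbind, lapply(mols, function(m) m$vel))
  sys$sites$vx <- vel[, 1]; sys$sites$vy <- vel[, 2]; sys$sites$vz <- vel[, 3]
  sys
}
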
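#' Write a trajectory to a plain-text file
#'
#' Versioned, self-describing line-oriented format (units nm, s, pN):
#' a header, then per frame the filament bead records, bound-element
#' records and the per-compartment species table. Coordinates are written
#' at full precision (`%.17g`), so a write/read round trip is lossless.
#'
#' @param traj A `cmTrajectory`, or a list of `cmFrame`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  frames <- if (inherits(traj, "cmTrajectory")) traj$frames else traj
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# cytomech trajectory v1", "# units: nm s pN",
               sprintf("nframes %d", length(frames))), con)
  for (fr in frames) writeFrame(fr, con)
  invisible(path)
}

#' @rdname writeTrajectory
#' @param frame A `cmFrame`.
#' @param con A writable connection.
#' @export
writeFrame <- function(frame, con) {
  num <- function(x) sprintf("%.17g", x)
  writeLines(sprintf("frame time %s nfil %d", num(frame$time),
                     length(frame$filaments)), con)
  for (f in frame$filaments) {
    writeLines(sprintf("filament %d minus_abs %d nmono %s", f$id,
                       as.integer(f$minus_abs),
                       paste(f$nmono, collapse = ",")), con)
    writeLines(apply(f$beads, 1, function(r) paste(num(r), collapse = " ")),
               con)
  }
  el <- frame$elements
  writeLines(sprintf("elements %d", nrow(el)), con)
  if (nrow(el) > 0)
    writeLines(sprintf("%s %d %s %d %s %d %s", el$kind, el$filA,
                       num(el$posA), el$filB, num(el$posB), el$nheads,
                       num(el$load)), con)
  sp <- frame$species
  writeLines(sprintf("species %d", nrow(sp)), con)
  writeLines(apply(sp, 1, paste, collapse = " "), con)
  invisible(NULL)
}

#' Read a trajectory written by [writeTrajectory()]
#'
#' @param path Input file.
#' @return List of `cmFrame`s with a `times` attribute.
#' @export
readTrajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "# cytomech trajectory v1")
    stop("not a cytomech trajectory file (version mismatch?)")
  i <- 3
  nfr <- as.integer(sub("nframes ", "", lines[i]))
  i <- i + 1
  frames <- vector("list", nfr)
  need <- function(n) {
    if (i + n - 1 > length(lines)) stop("truncated trajectory file")
  }
  for (k in seq_len(nfr)) {
    need(1)
    hdr <- strsplit(lines[i], " ")[[1]]
    if (hdr[1] != "frame") stop("malformed frame header at line ", i)
    tme <- as.numeric(hdr[3])
    nfil <- as.integer(hdr[5])
    i <- i + 1
    fils <- vector("list", nfil)
    for (fi in seq_len(nfil)) {
      need(1)
      fh <- strsplit(lines[i], " ")[[1]]
      if (fh[1] != "filament") stop("malformed filament record at line ", i)
      id <- as.integer(fh[2])
      minus_abs <- as.integer(fh[4])
      nmono <- as.integer(strsplit(fh[6], ",")[[1]])
      i <- i + 1
      nb <- length(nmono) + 1
      need(nb)
      beads <- do.call(rbind, lapply(lines[i:(i + nb - 1)], function(l)
        as.numeric(strsplit(l, " ")[[1]])))
      i <- i + nb
      fils[[fi]] <- list(id = id, beads = beads, nmono = nmono,
                         minus_abs = minus_abs)
    }
    need(1)
    ne <- as.integer(sub("elements ", "", lines[i]))
    i <- i + 1
    if (ne > 0) {
      need(ne)
      parts <- strsplit(lines[i:(i + ne - 1)], " ")
      el <- data.frame(
        kind = vapply(parts, `[`, "", 1),
        filA = as.integer(vapply(parts, `[`, "", 2)),
        posA = as.numeric(vapply(parts, `[`, "", 3)),
        filB = as.integer(vapply(parts, `[`, "", 4)),
        posB = as.numeric(vapply(parts, `[`, "", 5)),
        nheads = as.integer(vapply(parts, `[`, "", 6)),
        load = as.numeric(vapply(parts, `[`, "", 7)))
      i <- i + ne
    } else {
      el <- data.frame(kind = character(0), filA = integer(0),
                       posA = numeric(0), filB = integer(0),
                       posB = numeric(0), nheads = integer(0),
                       load = numeric(0))
    }
    need(1)
    nsp <- as.integer(sub("species ", "", lines[i]))
    i <- i + 1
    need(nsp)
    sp <- do.call(rbind, lapply(lines[i:(i + nsp - 1)], function(l)
      as.integer(strsplit(l, " ")[[1]])))
    colnames(sp) <- c("actin", "linker", "motor")
    i <- i + nsp
    fr <- list(time = tme, filaments = fils, elements = el, species = sp)
    class(fr) <- "cmFrame"
    frames[[k]] <- fr
  }
  attr(frames, "times") <- vapply(frames, function(f) f$time, numeric(1))
  frames
}

#' Tabular export of analysis results
#'
#' One row per frame (Rg, S) or per lag (MSD), written as CSV.
#'
#' @param traj A `cmTrajectory`.
#' @param path Output CSV path.
#' @param metrics Character subset of `c("rg", "order", "msd")`.
#' @return The data.frame written, invisibly.
#' @export
writeAnalysis <- function(traj, path, metrics = c("rg", "order")) {
  out <- data.frame(time = traj$times)
  if ("rg" %in% metrics)
    out$rg <- vapply(traj$frames, radiusOfGyration, numeric(1))
  if ("order" %in% metrics)
    out$S <- vapply(traj$frames, function(f) orderParameter(f)$S, numeric(1))
  if ("msd" %in% metrics) {
    msd <- msdCurve(traj)
    utils::write.csv(msd, sub("\\.csv$", "_msd.csv", path),
                     row.names = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
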
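#' Read and write granule track tables
#'
#' The track CSV schema is granule_id, frame, t_s, x_px, y_px, s_um (plus
#' any extra columns, e.g. on_shaft); the same schema is accepted from real
#' tracking exports.
#'
#' @param tracks track data.frame.
#' @param file path.
#' @return `readTracksCsv()`: the track data.frame.
#' @export
writeTracksCsv <- function(tracks, file) {
  utils::write.csv(tracks, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTracksCsv
#' @export
readTracksCsv <- function(file) {
  tr <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("granule_id", "t_s", "s_um")
  if (!all(need %in% names(tr)))
    stop("track CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tr
}

#' Read and write protrusion event tables
#'
#' Schema: protrusion_id, birth_s, death_s, origin_s_um, max_length_um
#' (plus optional columns such as censored, lifetime_s).
#'
#' @param protrusions protrusion data.frame.
#' @param file path.
#' @return `readProtrusionsCsv()`: the protrusion data.frame.
#' @export
writeProtrusionsCsv <- function(protrusions, file) {
  utils::write.csv(protrusions, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeProtrusionsCsv
#' @export
readProtrusionsCsv <- function(file) {
  p <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("protrusion_id", "birth_s", "origin_s_um")
  if (!all(need %in% names(p)))
    stop("protrusion CSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  p
}

#' Write / read generator ground truth as JSON
#'
#' @param truth ground-truth list (see [groundTruth()]).
#' @param file path.
#' @return `readGroundTruthJson()`: the ground-truth list.
#' @export
writeGroundTruthJson <- function(truth, file) {
  jsonlite::write_json(truth, file, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(file)
}

#' @rdname writeGroundTruthJson
#' @export
readGroundTruthJson <- function(file) {
  tr <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (nm in c("docks", "classes", "protrusion_lengths"))
    if (!is.null(tr[[nm]])) tr[[nm]] <- as.data.frame(tr[[nm]])
  tr
}

#' Write / read an image stack as multi-page TIFF
#'
#' Stacks are written as 32-bit float TIFF, one page per frame. Intensities
#' are stored as fractions of the 16-bit camera range (value / 65535), the
#' convention [readStackTiff()] inverts; within that range the round trip is
#' exact to single-float precision.
#'
#' @param stack numeric array (rows x cols x frames).
#' @param file path.
#' @return `readStackTiff()`: the numeric array.
#' @export
writeStackTiff <- function(stack, file) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  if (max(stack) > 65535 || min(stack) < 0)
    warning("intensities outside [0, 65535] are clipped on writing")
  pages <- lapply(seq_len(d[3]), function(k)
    pmin(pmax(stack[, , k], 0), 65535) / 65535)
  tiff::writeTIFF(pages, file, bits.per.sample = 32L, reduce = FALSE)
  invisible(file)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages))) * 65535
}

#' Export a simulated recording to disk
#'
#' Writes the track CSV, protrusion CSV and ground-truth JSON of an
#' [AxonRecording-class] under a common file prefix.
#'
#' @param rec an [AxonRecording-class].
#' @param prefix path prefix; files `<prefix>_tracks.csv`,
#'   `<prefix>_protrusions.csv`, `<prefix>_truth.json` are created.
#' @return invisibly, the three file paths.
#' @export
exportRecording <- function(rec, prefix) {
  stopifnot(is(rec, "AxonRecording"))
  f <- paste0(prefix, c("_tracks.csv", "_protrusions.csv", "_truth.json"))
  writeTracksCsv(tracks(rec), f[1])
  writeProtrusionsCsv(protrusions(rec), f[2])
  writeGroundTruthJson(groundTruth(rec), f[3])
  invisible(f)
}
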
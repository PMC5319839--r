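# Decoder serialization: a documented, versioned plain-text (JSON)
# schema so sessions can hold decoders fixed across blocksets.

DECODER_SCHEMA_VERSION <- "1.0"

#' Serialize fitted decoders to a JSON file
#'
#' @param path output file
#' @param decoder a \linkS4class{KalmanDecoder}
#' @param hmm optional \linkS4class{ClickHMM}
#' @export
writeDecoderFile <- function(path, decoder, hmm = NULL) {
  obj <- list(
    schema = DECODER_SCHEMA_VERSION,
    kalman = list(
      A = decoder@A, W = decoder@W, H = decoder@H, Q = decoder@Q,
      K = decoder@K, selectedFeatures = decoder@selectedFeatures,
      baseline = decoder@baseline, binWidth = decoder@binWidth,
      decay = decoder@decay))
  if (!is.null(hmm))
    obj$hmm <- list(
      center = hmm@center, rotation = hmm@rotation,
      featureIndex = hmm@featureIndex,
      stateMeans = hmm@stateMeans,
      covMove = hmm@stateCovs[[1L]], covClick = hmm@stateCovs[[2L]],
      transition = hmm@transition, clickThreshold = hmm@clickThreshold,
      consecutiveBinsRequired = hmm@consecutiveBinsRequired)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read decoders back from a JSON file
#'
#' @param path file written by \code{\link{writeDecoderFile}}
#' @return list(decoder, hmm) with hmm possibly NULL
#' @export
readDecoderFile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, DECODER_SCHEMA_VERSION))
    stop("unsupported decoder schema version: ", obj$schema)
  k <- obj$kalman
  decoder <- new("KalmanDecoder",
                 A = as.matrix(k$A), W = as.matrix(k$W),
                 H = as.matrix(k$H), Q = as.matrix(k$Q),
                 K = as.matrix(k$K),
                 selectedFeatures = as.integer(k$selectedFeatures),
                 baseline = as.numeric(k$baseline),
                 binWidth = k$binWidth, decay = k$decay)
  hmm <- NULL
  if (!is.null(obj$hmm)) {
    h <- obj$hmm
    hmm <- new("ClickHMM",
               center = as.numeric(h$center),
               rotation = as.matrix(h$rotation),
               featureIndex = as.integer(h$featureIndex),
               stateMeans = as.matrix(h$stateMeans),
               stateCovs = list(move = as.matrix(h$covMove),
                                click = as.matrix(h$covClick)),
               transition = as.matrix(h$transition),
               clickThreshold = as.numeric(h$clickThreshold),
               consecutiveBinsRequired = as.integer(h$consecutiveBinsRequired))
  }
  list(decoder = decoder, hmm = hmm)
}
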
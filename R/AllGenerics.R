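## Accessor generics for SeizureExperiment. Slot access from user code should
## go through these.

#' Accessors for SeizureExperiment components
#'
#' @param x a \code{\linkS4class{SeizureExperiment}}.
#' @param value replacement value (a DataFrame or data.frame for
#'   \code{trials<-} / \code{seizures<-}).
#' @return \code{trials}, \code{seizures} and \code{frontLines} return
#'   DataFrames; \code{frameTimes} and \code{excludedFrames} return per-frame
#'   vectors; \code{frameRate} a scalar (Hz); \code{rois} the ROI table as a
#'   data.frame; \code{lfpProxy} the LFP proxy list; \code{groundTruth} the
#'   simulation ground-truth list (empty for real data).
#' @name SeizureExperiment-accessors
#' @aliases trials seizures frontLines frameRate frameTimes excludedFrames
#'   rois lfpProxy groundTruth trials<- seizures<-
#' @examples
#' expt <- simulateExperiment(simConfig(n_neurons = 20, duration = 100,
#'                                      injection_time = 20,
#'                                      seizure_times = 50,
#'                                      seizure_duration = 10, seed = 1))
#' frameRate(expt)
#' head(trials(expt))
NULL

#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("trials<-", function(x, value) standardGeneric("trials<-"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("seizures", function(x) standardGeneric("seizures"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("seizures<-", function(x, value) standardGeneric("seizures<-"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("frontLines", function(x) standardGeneric("frontLines"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("excludedFrames", function(x) standardGeneric("excludedFrames"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("rois", function(x) standardGeneric("rois"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("lfpProxy", function(x) standardGeneric("lfpProxy"))
#' @rdname SeizureExperiment-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SeizureExperiment-accessors
setMethod("trials", "SeizureExperiment", function(x) x@trials)

#' @rdname SeizureExperiment-accessors
setReplaceMethod("trials", "SeizureExperiment", function(x, value) {
  x@trials <- S4Vectors::DataFrame(value)
  validObject(x)
  x
})

#' @rdname SeizureExperiment-accessors
setMethod("seizures", "SeizureExperiment", function(x) x@seizures)

#' @rdname SeizureExperiment-accessors
setReplaceMethod("seizures", "SeizureExperiment", function(x, value) {
  x@seizures <- S4Vectors::DataFrame(value)
  validObject(x)
  x
})

#' @rdname SeizureExperiment-accessors
setMethod("frontLines", "SeizureExperiment", function(x) x@frontLines)

#' @rdname SeizureExperiment-accessors
setMethod("frameRate", "SeizureExperiment", function(x)
  S4Vectors::metadata(x)$frame_rate)

#' @rdname SeizureExperiment-accessors
setMethod("frameTimes", "SeizureExperiment", function(x)
  SummarizedExperiment::colData(x)$time)

#' @rdname SeizureExperiment-accessors
setMethod("excludedFrames", "SeizureExperiment", function(x)
  SummarizedExperiment::colData(x)$excluded)

#' @rdname SeizureExperiment-accessors
setMethod("rois", "SeizureExperiment", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname SeizureExperiment-accessors
setMethod("lfpProxy", "SeizureExperiment", function(x) x@lfp)

#' @rdname SeizureExperiment-accessors
setMethod("groundTruth", "SeizureExperiment", function(x) x@groundTruth)
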
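#' @name accessors
#' @title Accessors for dirsynth objects
#' @description Small accessor generics for the package's S4 containers.
#' @param x an object.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("brainMask", function(x, ...) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("lesionMask", function(x, ...) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setGeneric("lesionMeta", function(x, ...) standardGeneric("lesionMeta"))
#' @rdname accessors
#' @export
setGeneric("tissueTable", function(x, ...) standardGeneric("tissueTable"))
#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(x, ...) standardGeneric("tissueLabels"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x, ...) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("channelData", function(x, ...) standardGeneric("channelData"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("nParameters", function(x, ...) standardGeneric("nParameters"))

#' @rdname accessors
#' @export
setMethod("brainMask", "TissuePhantom", function(x, ...) x@brainMask)
#' @rdname accessors
#' @export
setMethod("brainMask", "ChannelStack", function(x, ...) x@mask)
#' @rdname accessors
#' @export
setMethod("lesionMask", "TissuePhantom", function(x, ...) x@lesionMask)
#' @rdname accessors
#' @export
setMethod("lesionMeta", "TissuePhantom", function(x, ...) x@lesionMeta)
#' @rdname accessors
#' @export
setMethod("tissueTable", "TissuePhantom", function(x, ...) x@tissueTable)
#' @rdname accessors
#' @export
setMethod("tissueLabels", "TissuePhantom", function(x, ...) x@labels)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "TissuePhantom", function(x, ...) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ChannelStack", function(x, ...) x@spacing)
#' @rdname accessors
#' @export
setMethod("channelData", "ChannelStack", function(x, ...) x@data)
#' @rdname accessors
#' @export
setMethod("channelNames", "ChannelStack", function(x, ...) x@channels)

#' Extract one channel of a stack as a 3D array
#'
#' @param x a [ChannelStack-class].
#' @param channel channel name or index.
#' @return numeric 3D array.
#' @export
getChannel <- function(x, channel) {
  stopifnot(is(x, "ChannelStack"))
  if (is.character(channel)) {
    channel <- match(channel, x@channels)
    if (is.na(channel)) stop("unknown channel name")
  }
  x@data[, , , channel, drop = TRUE]
}

setMethod("show", "TissuePhantom", function(object) {
  d <- dim(object@labels)
  cat(sprintf("TissuePhantom: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  brain voxels: %d; lesions: %d\n", sum(object@brainMask),
              nrow(object@lesionMeta)))
  cat(sprintf("  tissues: %s\n", paste(object@tissueTable$name,
                                       collapse = ", ")))
})

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ChannelStack: %d x %d x %d voxels, %d channel(s): %s\n",
              d[1], d[2], d[3], d[4], paste(object@channels,
                                            collapse = ", ")))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult [%s]: TP %d, FP %d, FN %d\n", object@subject,
              object@tp, object@fp, object@fn))
})

setMethod("show", "IccResult", function(object) {
  cat(sprintf(
    "ICC (two-way mixed, absolute agreement, single measure): %.3f\n",
    object@icc))
  cat(sprintf("  95%% CI [%.3f, %.3f]; F(%.0f, %.1f) = %.3f, p = %.3g\n",
              object@ciLow, object@ciHigh, object@df1, object@df2,
              object@fStat, object@p))
  cat(sprintf("  n = %d subjects, k = %d methods\n", object@n, object@k))
})
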
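#' Accessors for ppcmv classes
#'
#' @param object a ppcmv S4 object.
#' @name ppcmv-accessors
NULL

#' @rdname ppcmv-accessors
#' @return `pixels()`: the intensity matrix of an [EnFaceImage-class].
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname ppcmv-accessors
#' @return `mmPerPx()`: physical scale, millimetres per pixel.
#' @export
setGeneric("mmPerPx", function(object) standardGeneric("mmPerPx"))

#' @rdname ppcmv-accessors
#' @return `roiMasks()`: named list of logical ROI masks of an
#'   [RoiSet-class].
#' @export
setGeneric("roiMasks", function(object) standardGeneric("roiMasks"))

#' @rdname ppcmv-accessors
#' @return `roiTable()`: the per-ROI `data.frame` of a
#'   [DensityReport-class].
#' @export
setGeneric("roiTable", function(object) standardGeneric("roiTable"))

#' @rdname ppcmv-accessors
#' @return `threshold()`: the Otsu threshold in \[0, 1\].
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))

#' @rdname ppcmv-accessors
#' @return `bias()`: the Bland-Altman mean difference.
#' @export
setGeneric("bias", function(object) standardGeneric("bias"))

#' @rdname ppcmv-accessors
#' @return `limitsOfAgreement()`: numeric of length 2, the lower and upper
#'   95% limits of agreement.
#' @export
setGeneric("limitsOfAgreement",
           function(object) standardGeneric("limitsOfAgreement"))
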
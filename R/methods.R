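#' @include AllClasses.R AllGenerics.R
NULL

setMethod("insideSeeds", "SeedSet", function(x) x@inside)
setMethod("outsideSeeds", "SeedSet", function(x) x@outside)
setMethod("nucleusMask", "SeedSet", function(x) x@nucleusRaw)

setMethod("wbcLabels", "SegmentationResult", function(x) x@wbcLabels)
setMethod("nucleusLabels", "SegmentationResult", function(x) x@nucleusLabels)
setMethod("regionTable", "SegmentationResult", function(x) x@props)

setMethod("wbcLabels", "SyntheticSmear", function(x) x@wbcLabels)
setMethod("nucleusLabels", "SyntheticSmear", function(x) x@nucleusLabels)
setMethod("smearImage", "SyntheticSmear", function(x) x@image)
setMethod("cellRecords", "SyntheticSmear", function(x) x@cells)

setMethod("metrics", "EvalReport", function(x) {
  c(tp = x@tp, fp = x@fp, fn = x@fn,
    overseg = x@overseg, underseg = x@underseg,
    precision = x@precision, recall = x@recall, f1 = x@f1)
})

setMethod("show", "SeedSet", function(object) {
  d <- dim(object@inside)
  nIn <- if (length(object@inside)) max(.cpp_label(storage0(object@inside), 4L)) else 0L
  cat("SeedSet ", d[1], "x", d[2],
      ": ", nIn, " inside seed component(s), ",
      sum(object@outside), " outside-seed px\n", sep = "")
})

setMethod("show", "SegmentationResult", function(object) {
  k <- max(0L, object@wbcLabels)
  cat("SegmentationResult: ", k, " white blood cell(s)\n", sep = "")
  if (k > 0) {
    tab <- table(factor(object@provenance,
                        c("single", "split_pass1", "split_pass2")))
    cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    cat("  mean area:", round(mean(object@props$area), 1),
        " mean roundness:", round(mean(object@props$roundness), 2), "\n")
  }
})

setMethod("show", "SyntheticSmear", function(object) {
  d <- dim(object@image)
  cat("SyntheticSmear ", d[1], "x", d[2], ": ",
      nrow(object@cells), " WBC(s), seed ",
      object@spec$seed, "\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport: TP=", object@tp, " FP=", object@fp, " FN=", object@fn,
      " overseg=", object@overseg, " underseg=", object@underseg, "\n",
      "  P=", sprintf("%.1f%%", 100 * object@precision),
      " R=", sprintf("%.1f%%", 100 * object@recall),
      " F1=", sprintf("%.1f%%", 100 * object@f1), "\n", sep = "")
})

# integer storage for masks passed to compiled code
storage0 <- function(m) {
  storage.mode(m) <- "integer"
  m
}
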
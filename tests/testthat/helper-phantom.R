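# Shared phantom fixtures, memoised so repeated tests do not regenerate the
# same volumes. The "small" phantom (96^3) keeps unit tests fast; acceptance
# tests use the default 160^3 conditions.

.fixtureCache <- new.env(parent = emptyenv())

smallPhantomSpec <- function(...) {
  args <- utils::modifyList(
    list(preset = "ellipsoid", shape = c(96L, 96L, 96L),
         brainSemiAxes = c(30, 28, 28), wallMm = 4, fatMm = 3,
         muscleSemiAxes = c(12, 5, 14), faceMm = 10),
    list(...))
  do.call(phantomSpec, args)
}

smallPhantom <- function() {
  if (is.null(.fixtureCache$small))
    .fixtureCache$small <- makePhantom(smallPhantomSpec())
  .fixtureCache$small
}

defaultPhantom <- function() {
  if (is.null(.fixtureCache$default))
    .fixtureCache$default <- makePhantom(phantomSpec("ellipsoid"))
  .fixtureCache$default
}

# 2-D annulus embedded as one slice of a thin 3-D mask
annulusSlice <- function(n = 100, rOuter = 40, rInner = 35,
                         cx = (n + 1) / 2, cy = (n + 1) / 2) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  matrix(as.integer(r <= rOuter & r >= rInner), n, n)
}
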
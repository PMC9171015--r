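# shared in-code fixtures

# nuclear maturation contingency table (MII vs abnormal, 5 groups)
nuclearMaturationCounts <- function() {
  GroupCounts(matrix(
    c(72, 76, 72, 81, 3,
      18, 14, 16, 20, 94), ncol = 2,
    dimnames = list(c("control", "vehicle", "1e-9 M", "1e-7 M", "1e-5 M"),
                    c("MII", "abnormal"))))
}

# a small disc image: uniform foreground on a dark background
discPlane <- function(side, radius, fg = 1000, bg = 0) {
  c0 <- (side + 1) / 2
  d2 <- outer((seq_len(side) - c0)^2, (seq_len(side) - c0)^2, `+`)
  plane <- matrix(bg, side, side)
  plane[d2 <= radius^2] <- fg
  plane
}

extdata <- function(name) {
  p <- system.file("extdata", name, package = "cocQuant")
  stopifnot(nzchar(p))
  p
}
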
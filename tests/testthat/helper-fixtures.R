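# in-code fixtures shared across the suite

# horizontal bright bar of full width `fw` on a zero background
bar_image <- function(fw, H = 2 * fw + 40, W = 160, value = 100) {
  r0 <- floor(H / 2 - fw / 2) + 1L
  img <- matrix(0, H, W)
  img[r0:(r0 + fw - 1L), ] <- value
  attr(img, "center_row") <- r0 + fw / 2 - 0.5
  attr(img, "rows") <- c(r0, r0 + fw - 1L)
  img
}

# the two-scale fixture: a 4 px and a 30 px bar in one frame
two_bar_image <- function(H = 120, W = 160, value = 100) {
  img <- matrix(0, H, W)
  img[20:23, ] <- value
  img[70:99, ] <- value
  img
}

# uniform-colour frame
flat_frame <- function(r, g, b, H = 8, W = 8) {
  px <- array(0, c(H, W, 3))
  px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- b
  frame(px)
}

# a small synthetic frame with blue background and one gray rectangle
rect_frame <- function(H = 60, W = 80, rows = 20:40, cols = 30:50) {
  px <- array(0, c(H, W, 3))
  px[, , 1] <- 35; px[, , 2] <- 55; px[, , 3] <- 190
  for (ch in 1:3) px[rows, cols, ch] <- c(180, 170, 160)[ch]
  frame(px)
}

random_mask <- function(H, W, p = 0.5) {
  matrix(as.integer(stats::runif(H * W) < p), H, W)
}
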
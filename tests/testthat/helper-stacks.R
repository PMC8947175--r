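# Tiny analytic stacks used by calibration / subtraction unit tests: a
# square "nucleus" (H2B-positive) and a separate bar "mitochondrion"
# (Hsp60-positive), with the dsDNA channel built from stated ratios.
toy_control <- function(bx = 2, by = 3, size = 48, pixel = 0.5,
                        id = "toy") {
  h2b <- matrix(0, size, size)
  h2b[5:16, 5:16] <- 1
  hsp60 <- matrix(0, size, size)
  hsp60[30:34, 8:40] <- 1
  hsp60[31:33, 20:28] <- 1.6          # nucleoid-like hot stripe
  dsdna <- by * h2b + bx * hsp60
  channel_stack(dsdna, h2b, hsp60, pixel_size_um = pixel, image_id = id)
}

# a blank square field
blank_mat <- function(size = 32) matrix(0, size, size)
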
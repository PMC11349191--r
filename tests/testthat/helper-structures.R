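# Compact builders for tiny hand-specified structures.

# atoms: list of c(name, element, resname, resnum, chain, x, y, z)
mini_structure <- function(...) {
  rows <- list(...)
  tab <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r[[1]], element = r[[2]],
               resname = r[[3]], resnum = as.integer(r[[4]]),
               chain = r[[5]], insert = "", altloc = "", occupancy = 1,
               bfactor = 0,
               x = as.numeric(r[[6]]), y = as.numeric(r[[7]]),
               z = as.numeric(r[[8]]), stringsAsFactors = FALSE)
  }))
  wb_structure(tab[, 1:10], as.matrix(tab[, c("x", "y", "z")]))
}

# One water (O + 2 H) at a position, ideal internal geometry, H1 along +x.
water_at <- function(pos, resnum, chain = "W") {
  h2 <- c(cos(104.5 * pi / 180), 0, sin(104.5 * pi / 180))
  list(
    list("O", "O", "HOH", resnum, chain, pos[1], pos[2], pos[3]),
    list("H1", "H", "HOH", resnum, chain, pos[1] + 0.96, pos[2], pos[3]),
    list("H2", "H", "HOH", resnum, chain, pos[1] + 0.96 * h2[1], pos[2],
         pos[3] + 0.96 * h2[3]))
}
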
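# Shared fixture builders.

# a donor-H ... acceptor triple with controlled geometry: donor O at the
# origin, H on the x-axis at 0.96 A, acceptor O placed so that d(D,A) and the
# D-H-A angle take the requested values
hbond_fixture <- function(d_DA, angle_deg) {
  dDH <- 0.96
  th <- angle_deg * pi / 180
  # law of cosines on the D-H-A triangle (angle at H)
  dHA <- dDH * cos(th) + sqrt(pmax(d_DA^2 - dDH^2 * sin(th)^2, 0))
  H <- c(dDH, 0, 0)
  A <- H + dHA * c(cos(pi - th), sin(pi - th), 0)
  topo <- mol_structure(c("O", "H", "O"),
                        rbind(c(0, 0, 0), H, A),
                        role = c("solute", "solute", "water_oxygen"),
                        bonds = rbind(c(1L, 2L)))
  trajectory(topo, list(topo$xyz))
}
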
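# Coarse rigid guest models spanning the three chemotherapeutic size
# classes screened for pancreatic-cancer delivery: a small one-site
# gemcitabine-like guest, a medium three-site SN-38-like guest and a bulky
# five-site paclitaxel-like guest, plus a unit Lennard-Jones sphere for
# analytic oracles. Molar masses equal the real drugs' formula masses
# (C9H11F2N3O4, C22H20N2O5, C47H51NO14); geometries are coarse beads, not
# conformers.

#' Rigid guest model library
#'
#' @param ff A [forcefield()] providing the guest site parameters.
#' @return Named list of [rigid_guest()]: `gemcitabine_like` (263.2 g/mol,
#'   1 site), `sn38_like` (392.4 g/mol, 3 sites), `paclitaxel_like`
#'   (853.9 g/mol, 5 sites), `unit` (single LJ sphere for tests). Minimal
#'   diameters increase in that drug order.
#' @examples
#' guests <- make_guest_models()
#' sapply(guests, function(g) g$minimal_diameter)
#' @export
make_guest_models <- function(ff = forcefield()) {
  gem <- rigid_guest("gemcitabine_like",
                     data.frame(type = "guest_small", x = 0, y = 0, z = 0),
                     molar_mass = 263.2, ff = ff)
  # equilateral triangle, circumradius 2.5 A
  tri <- 2.5
  sn38 <- rigid_guest("sn38_like",
                      data.frame(type = "guest_medium",
                                 x = tri * cos(2 * pi * (0:2) / 3),
                                 y = tri * sin(2 * pi * (0:2) / 3),
                                 z = 0),
                      molar_mass = 392.4, ff = ff)
  # center + tetrahedron, radius 3.2 A
  tet <- 3.2 / sqrt(3)
  pac <- rigid_guest("paclitaxel_like",
                     data.frame(type = "guest_bulky",
                                x = c(0, tet * c(1, 1, -1, -1)),
                                y = c(0, tet * c(1, -1, 1, -1)),
                                z = c(0, tet * c(1, -1, -1, 1))),
                     molar_mass = 853.9, ff = ff)
  unit <- rigid_guest("unit_sphere",
                      data.frame(type = "guest_unit", x = 0, y = 0, z = 0),
                      molar_mass = 100, ff = ff)
  list(gemcitabine_like = gem, sn38_like = sn38, paclitaxel_like = pac,
       unit = unit)
}
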
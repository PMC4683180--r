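# Redox-thermodynamics engine for nitrate-dependent AOM.
#
# Standard-state free energy of an n-electron transfer between half-reaction
# couples: deltaE0' = E0'(acceptor) - E0'(donor), deltaG0' = -n F deltaE0'.
# Potentials are stored in millivolts exactly as tabulated and converted to
# volts only inside the free-energy computation, so printed values stay
# exact. On top of the pairwise engine sit the per-CH4 electron ledger of
# reverse methanogenesis and the ion-translocation (proton-motive-force)
# bookkeeping of the membrane complexes.

#' Faraday constant, kJ mol-1 V-1
#' @export
FARADAY_KJ_PER_MOL_V <- 96.485

# classification tolerance on deltaG0', kJ
.DG_TOL <- 1e-9

#' Construct a redox couple
#'
#' @param name Couple label (e.g. `"NO3-/NO2-"`).
#' @param e0_prime_mv Standard redox potential at pH 7, in mV.
#' @param n_electrons Electrons transferred per couple turnover, >= 1.
#' @return One-row data.frame.
#' @export
redox_couple <- function(name, e0_prime_mv, n_electrons = 2L) {
  stopifnot(n_electrons >= 1)
  data.frame(name = name, e0_prime_mv = e0_prime_mv,
             n_electrons = n_electrons, stringsAsFactors = FALSE)
}

#' Default redox-couple table
#'
#' Reads the couple table shipped with the package. It holds the standard
#' (pH 7) potentials this reconstruction is built on: NO3-/NO2- +433 mV,
#' CO2/CH4 -244 mV, CoM-S-S-CoB/CoM-SH+CoB-SH -143 mV, menaquinone -80 mV,
#' methanophenazine -165 mV, F420/F420H2 -360 mV and ferredoxin about
#' -500 mV.
#'
#' @return data.frame with `name`, `e0_prime_mv`, `n_electrons`.
#' @export
default_redox_couples <- function() {
  path <- system.file("extdata", "redox_couples.tsv",
                      package = "methanoredox", mustWork = TRUE)
  read_redox_table(path)
}

#' Look up a couple by name
#'
#' @param couples Couple table.
#' @param name Couple name.
#' @return One-row data.frame.
#' @export
get_couple <- function(couples, name) {
  i <- which(couples$name == name)
  if (!length(i)) stop("unknown redox couple: '", name, "'")
  couples[i[1], , drop = FALSE]
}

.classify_dg <- function(dg) {
  if (dg < -.DG_TOL) "EXERGONIC"
  else if (dg > .DG_TOL) "ENDERGONIC"
  else "ISOERGONIC"
}

#' Free energy of an n-electron transfer between two redox couples
#'
#' @param n_electrons Electrons transferred, >= 1.
#' @param donor,acceptor Redox couples ([redox_couple()] rows or anything
#'   with `name` and `e0_prime_mv`).
#' @return List of class `reaction_energy` with `donor`, `acceptor`,
#'   `n_electrons`, `delta_e_mv` (acceptor minus donor), `delta_g0_kj`
#'   (`-n F deltaE`, full precision) and `classification` (`EXERGONIC`,
#'   `ENDERGONIC` or `ISOERGONIC` by the sign of deltaG0').
#' @examples
#' couples <- default_redox_couples()
#' delta_g(8, get_couple(couples, "CO2/CH4"), get_couple(couples, "NO3-/NO2-"))
#' @export
delta_g <- function(n_electrons, donor, acceptor) {
  stopifnot(n_electrons >= 1)
  de <- acceptor$e0_prime_mv[[1]] - donor$e0_prime_mv[[1]]
  dg <- -n_electrons * FARADAY_KJ_PER_MOL_V * de / 1000
  structure(list(donor = donor$name[[1]], acceptor = acceptor$name[[1]],
                 n_electrons = n_electrons, delta_e_mv = de,
                 delta_g0_kj = dg, classification = .classify_dg(dg)),
            class = "reaction_energy")
}

#' @export
print.reaction_energy <- function(x, ...) {
  cat(sprintf("%d e-: %s -> %s | deltaE0' = %+g mV | deltaG0' = %+d kJ/mol (%s)\n",
              x$n_electrons, x$donor, x$acceptor, x$delta_e_mv,
              as.integer(round(x$delta_g0_kj)), x$classification))
  invisible(x)
}

#' Classify a 2-electron transfer between two couples
#'
#' @inheritParams delta_g
#' @return `"EXERGONIC"`, `"ENDERGONIC"` or `"ISOERGONIC"`.
#' @examples
#' thiols <- redox_couple("CoM-S-S-CoB/CoM-SH+CoB-SH", -143)
#' classify_transfer(thiols, redox_couple("menaquinone", -80))
#' @export
classify_transfer <- function(donor, acceptor) {
  delta_g(2, donor, acceptor)$classification
}

#' Free energy of a coupled (bifurcating/confurcating) reaction
#'
#' Sums the standard-state free energies of several simultaneous electron
#' transfers, e.g. the proposed electron confurcation in which the
#' endergonic oxidation of the thiol cofactors (CoM-SH/CoB-SH) by F420 is
#' coupled to the exergonic oxidation of reduced ferredoxin by F420. The
#' per-branch breakdown and the classification of the total are returned;
#' the engine reports the computed value even when it disagrees with a
#' qualitative feasibility expectation (standard-state potentials need not
#' reflect physiological concentrations).
#'
#' @param branches List of branches, each `list(n_electrons, donor,
#'   acceptor)`.
#' @return List with `branches` (data.frame breakdown), `total_dg0_kj` and
#'   `classification`.
#' @export
coupled_reaction_dg <- function(branches) {
  stopifnot(length(branches) >= 1)
  rows <- lapply(branches, function(b) {
    re <- delta_g(b[[1]], b[[2]], b[[3]])
    data.frame(donor = re$donor, acceptor = re$acceptor,
               n_electrons = re$n_electrons, delta_e_mv = re$delta_e_mv,
               delta_g0_kj = re$delta_g0_kj,
               classification = re$classification,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  total <- sum(rows$delta_g0_kj)
  list(branches = rows, total_dg0_kj = total,
       classification = .classify_dg(total))
}

#' Per-CH4 electron ledger of reverse methanogenesis
#'
#' Methane oxidation through the reversed methanogenesis pathway releases 8
#' electrons per CH4 onto cytoplasmic carriers: by default 2 F420H2 (4 e-),
#' 1 reduced ferredoxin (2 e-) and 1 CoM-SH/CoB-SH thiol pair (2 e-). On
#' the acceptor side each NO3- -> NO2- reduction consumes 2 e-, so 4
#' nitrate are reduced per CH4. Electron conservation is enforced: a custom
#' stoichiometry whose donated and accepted electrons disagree is rejected
#' with the imbalance named.
#'
#' @param stoichiometry Optional list with `f420h2`, `fd_red`,
#'   `thiol_pairs` (mol carrier per CH4, each carrying 2 e-/mol) and
#'   `nitrate` (mol NO3- reduced to NO2- per CH4, 2 e- each).
#' @return List of class `electron_ledger` with `flows` (data.frame
#'   `carrier`, `mols_per_ch4`, `electrons_per_ch4`), `total_donated`,
#'   `total_accepted`.
#' @export
reverse_methanogenesis_ledger <- function(stoichiometry = NULL) {
  s <- modifyList(list(f420h2 = 2L, fd_red = 1L, thiol_pairs = 1L,
                       nitrate = 4L),
                  if (is.null(stoichiometry)) list() else stoichiometry)
  flows <- data.frame(
    carrier = c("F420H2", "Fdred", "CoM-SH/CoB-SH"),
    mols_per_ch4 = c(s$f420h2, s$fd_red, s$thiol_pairs),
    electrons_per_ch4 = 2L * c(s$f420h2, s$fd_red, s$thiol_pairs),
    stringsAsFactors = FALSE
  )
  donated <- sum(flows$electrons_per_ch4)
  accepted <- 2L * s$nitrate
  if (donated != accepted) {
    stop("electron ledger not conserved: ", donated,
         " e- donated by carriers but ", accepted,
         " e- accepted by ", s$nitrate, " NO3- -> NO2-")
  }
  structure(list(flows = flows, total_donated = donated,
                 total_accepted = accepted, n_nitrate = s$nitrate),
            class = "electron_ledger")
}

#' Default membrane pump stoichiometries
#'
#' Charges translocated per 2 electrons for each membrane complex:
#' F420H2 dehydrogenase (Fqo) up to 3 H+/2e- when reducing menaquinone;
#' Rieske/cytochrome-b complex 4 H+/2e- via the Q-cycle; membrane
#' heterodisulfide reductase (Hdr) 0 (enabled, but whether it pumps is
#' unknown); nitrate reductase (Nar) 0 and disabled (whether pseudo-
#' periplasmic nitrate reduction contributes to the gradient is open).
#'
#' @return data.frame with `step`, `charges_per_2e`, `enabled`.
#' @export
default_pumps <- function() {
  data.frame(step = c("Fqo", "Rieske", "Hdr", "Nar"),
             charges_per_2e = c(3, 4, 0, 0),
             enabled = c(TRUE, TRUE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

#' Default electron routing through the membrane pumps
#'
#' F420H2 electrons pass the F420H2 dehydrogenase and then the Rieske/cyt-b
#' complex; thiol electrons pass the membrane heterodisulfide reductase and
#' then the Rieske/cyt-b complex; ferredoxin re-oxidation is left unrouted
#' (cytoplasmic recycling, no membrane contribution).
#'
#' @return Named list mapping carrier name to a character vector of pump
#'   steps.
#' @export
default_routing <- function() {
  list("F420H2" = c("Fqo", "Rieske"),
       "CoM-SH/CoB-SH" = c("Hdr", "Rieske"),
       "Fdred" = character(0))
}

#' Proton-motive-force ledger per CH4
#'
#' Tallies signed translocated charges per mol CH4. Methyl transfer by the
#' Mtr complex imports a fixed 2 Na+ per CH4 during reverse methanogenesis
#' (a per-CH4 gradient cost of -2 charges, independent of electron
#' routing); each pump step contributes `charges_per_2e x (electrons routed
#' / 2)`. Na+ and H+ are summed as indistinguishable charges, since the
#' ATP synthase can use both gradients. Routing electrons through a
#' disabled pump is an error.
#'
#' @param ledger An [reverse_methanogenesis_ledger()] result.
#' @param pumps Pump table ([default_pumps()]).
#' @param routing Carrier-to-pump-chain map ([default_routing()]).
#' @param mtr_charges_per_ch4 Fixed Mtr gradient cost per CH4.
#' @return List of class `pmf_ledger` with `steps` (data.frame `step`,
#'   `electrons_routed`, `charges`), `mtr_charges` and `net_charges`.
#' @export
pmf_balance <- function(ledger, pumps = default_pumps(),
                        routing = default_routing(),
                        mtr_charges_per_ch4 = -2) {
  stopifnot(inherits(ledger, "electron_ledger"))
  electrons <- stats::setNames(rep(0, nrow(pumps)), pumps$step)
  for (carrier in names(routing)) {
    chain <- routing[[carrier]]
    if (!length(chain)) next
    i <- match(carrier, ledger$flows$carrier)
    if (is.na(i)) stop("routing names unknown carrier '", carrier, "'")
    e <- ledger$flows$electrons_per_ch4[i]
    unknown <- setdiff(chain, pumps$step)
    if (length(unknown)) stop("routing names unknown pump '", unknown[1], "'")
    disabled <- chain[!pumps$enabled[match(chain, pumps$step)]]
    if (length(disabled)) {
      stop(e, " e- from ", carrier, " routed through disabled pump '",
           disabled[1], "'")
    }
    electrons[chain] <- electrons[chain] + e
  }
  steps <- data.frame(step = pumps$step,
                      electrons_routed = unname(electrons[pumps$step]),
                      charges = pumps$charges_per_2e *
                        unname(electrons[pumps$step]) / 2,
                      stringsAsFactors = FALSE)
  net <- mtr_charges_per_ch4 + sum(steps$charges)
  structure(list(steps = steps, mtr_charges = mtr_charges_per_ch4,
                 net_charges = net),
            class = "pmf_ledger")
}

#' @export
print.pmf_ledger <- function(x, ...) {
  cat("Mtr (fixed per CH4):", sprintf("%+g", x$mtr_charges), "charges\n")
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("%-8s %2g e- -> %+g charges\n", x$steps$step[i],
                x$steps$electrons_routed[i], x$steps$charges[i]))
  }
  cat("net:", sprintf("%+g", x$net_charges), "charges per CH4\n")
  invisible(x)
}
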
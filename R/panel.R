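#' Metabolite panel: components, spin systems, study conditions
#'
#' A panel describes the composition model of the artificial-urine system:
#' which components (active/passive metabolites, inorganic ions, protein) are
#' present, their physiological concentration ranges in uM, the 1H spin
#' systems they contribute (multiplicity, couplings, reference shift, search
#' window), which five spin systems serve as navigator signals, the buffered
#' pH range and the acquisition temperature levels.
#'
#' @name nmr_panel
#' @keywords internal
NULL

PANEL_FORMAT_VERSION <- "1.0"

panel_new <- function(components, spin_systems, ph_range, temp_levels_K) {
  structure(list(components = components,
                 spin_systems = spin_systems,
                 ph_range = as.numeric(ph_range),
                 temp_levels_K = as.numeric(temp_levels_K),
                 version = PANEL_FORMAT_VERSION),
            class = "nmr_panel")
}

#' Validate a panel against its invariants
#'
#' Checks window ordering, reference shifts inside windows, multiplicity and
#' coupling consistency, component/spin-system cross references, uniqueness
#' of ids, the pH range, and the navigator roster (exactly five navigator
#' spin systems: two citrate doublets of doublets, two creatinine singlets
#' and one glycine singlet, all on active metabolites).
#'
#' @param panel An `nmr_panel`.
#' @return The panel, invisibly; aborts with a message naming the offending
#'   field otherwise.
#' @export
validate_panel <- function(panel) {
  ss <- panel$spin_systems
  comp <- panel$components
  fail <- function(...) stop("panel validation: ", ..., call. = FALSE)

  req_ss <- c("id", "metabolite", "proton_label", "multiplicity", "n_protons",
              "delta_free", "window_lo", "window_hi", "is_navigator")
  for (f in req_ss) if (is.null(ss[[f]])) fail("spin_systems lacks field '", f, "'")
  req_c <- c("name", "role", "conc_min", "conc_max", "nmr_visible")
  for (f in req_c) if (is.null(comp[[f]])) fail("components lacks field '", f, "'")

  if (anyDuplicated(ss$id)) fail("spin_systems: duplicated id")
  if (anyDuplicated(comp$name)) fail("components: duplicated name")
  if (!all(ss$multiplicity %in% c("s", "d", "dd", "t", "m"))) {
    fail("spin_systems: multiplicity outside {s, d, dd, t, m}")
  }
  if (any(ss$window_lo >= ss$window_hi)) {
    fail("spin_systems: window_lo >= window_hi for ",
         ss$id[which(ss$window_lo >= ss$window_hi)[1]])
  }
  bad <- ss$delta_free < ss$window_lo | ss$delta_free > ss$window_hi
  if (any(bad)) fail("spin_systems: delta_free outside window for ",
                     ss$id[which(bad)[1]])
  if (any(ss$n_protons < 1)) fail("spin_systems: n_protons must be >= 1")
  for (i in seq_len(nrow(ss))) {
    if (ss$multiplicity[i] %in% c("d", "dd", "t") &&
        length(ss$j_hz[[i]]) < 1) {
      fail("spin_systems: j_hz required for multiplicity '",
           ss$multiplicity[i], "' (", ss$id[i], ")")
    }
  }

  if (!all(comp$role %in% c("active_metabolite", "passive_metabolite",
                            "inorganic_ion", "protein"))) {
    fail("components: unknown role")
  }
  if (any(comp$conc_min < 0)) fail("components: conc_min must be >= 0")
  if (any(comp$conc_min >= comp$conc_max)) {
    fail("components: conc_min must be < conc_max for ",
         comp$name[which(comp$conc_min >= comp$conc_max)[1]])
  }
  refs <- unlist(comp$spin_systems)
  if (!all(refs %in% ss$id)) {
    fail("components: unresolved spin system id '",
         setdiff(refs, ss$id)[1], "'")
  }
  if (anyDuplicated(refs)) {
    fail("components: spin system '", refs[duplicated(refs)][1],
         "' referenced by more than one component")
  }
  if (!setequal(refs, ss$id)) {
    fail("spin system(s) not attached to any component: ",
         paste(setdiff(ss$id, refs), collapse = ", "))
  }
  for (i in seq_len(nrow(comp))) {
    if (comp$role[i] == "inorganic_ion" && length(comp$spin_systems[[i]]) > 0) {
      fail("components: inorganic ion '", comp$name[i],
           "' must not carry spin systems")
    }
  }

  if (panel$ph_range[1] >= panel$ph_range[2] ||
      panel$ph_range[1] < 6.0 || panel$ph_range[2] > 8.0) {
    fail("ph_range must be increasing and within [6.0, 8.0]")
  }
  if (length(panel$temp_levels_K) < 1 || any(panel$temp_levels_K <= 0)) {
    fail("temp_levels_K must contain positive temperatures")
  }

  nav <- ss[ss$is_navigator, , drop = FALSE]
  owner <- function(id) comp$name[vapply(comp$spin_systems, function(x)
    id %in% x, logical(1))]
  nav_met <- tolower(vapply(nav$id, function(id) owner(id)[1], character(1)))
  n_cit <- sum(nav_met == "citrate" & nav$multiplicity == "dd")
  n_cre <- sum(nav_met == "creatinine" & nav$multiplicity == "s")
  n_gly <- sum(nav_met == "glycine" & nav$multiplicity == "s")
  if (nrow(nav) != 5 || n_cit != 2 || n_cre != 2 || n_gly != 1) {
    fail("panel lacks navigator signals ",
         "(need 2 citrate dd, 2 creatinine s, 1 glycine s)")
  }
  nav_roles <- comp$role[match(unique(vapply(nav$id, function(id) owner(id)[1],
                                             character(1))), comp$name)]
  if (!all(nav_roles == "active_metabolite")) {
    fail("navigator metabolites must have role active_metabolite")
  }
  invisible(panel)
}

#' Load a panel from a JSON configuration file
#'
#' The documented schema is the one produced by [write_panel()]: an object
#' with `components` (name, role, conc_range `[min, max]` in uM,
#' nmr_visible, spin_systems id list), `spin_systems` (id, metabolite,
#' proton_label, multiplicity, n_protons, j_hz list, delta_free, window
#' `[lo, hi]`, is_navigator), `ph_range`, `temp_levels_K` and `version`.
#'
#' @param path Path to the panel JSON file.
#' @return A validated `nmr_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("load_panel: file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  need <- c("components", "spin_systems", "ph_range", "temp_levels_K")
  for (f in need) if (is.null(raw[[f]])) {
    stop("panel validation: missing top-level field '", f, "'")
  }
  ssl <- raw$spin_systems
  ss <- data.frame(
    id = vapply(ssl, `[[`, character(1), "id"),
    metabolite = vapply(ssl, `[[`, character(1), "metabolite"),
    proton_label = vapply(ssl, `[[`, character(1), "proton_label"),
    multiplicity = vapply(ssl, `[[`, character(1), "multiplicity"),
    n_protons = vapply(ssl, function(x) as.integer(x$n_protons), integer(1)),
    delta_free = vapply(ssl, function(x) as.numeric(x$delta_free), numeric(1)),
    window_lo = vapply(ssl, function(x) as.numeric(x$window[1]), numeric(1)),
    window_hi = vapply(ssl, function(x) as.numeric(x$window[2]), numeric(1)),
    is_navigator = vapply(ssl, function(x) isTRUE(x$is_navigator), logical(1)),
    stringsAsFactors = FALSE)
  ss$j_hz <- lapply(ssl, function(x) as.numeric(unlist(x$j_hz)))

  cl <- raw$components
  comp <- data.frame(
    name = vapply(cl, `[[`, character(1), "name"),
    role = vapply(cl, `[[`, character(1), "role"),
    conc_min = vapply(cl, function(x) as.numeric(x$conc_range[1]), numeric(1)),
    conc_max = vapply(cl, function(x) as.numeric(x$conc_range[2]), numeric(1)),
    nmr_visible = vapply(cl, function(x) isTRUE(x$nmr_visible), logical(1)),
    stringsAsFactors = FALSE)
  comp$spin_systems <- lapply(cl, function(x) as.character(unlist(x$spin_systems)))

  panel <- panel_new(comp, ss, raw$ph_range, raw$temp_levels_K)
  validate_panel(panel)
  panel
}

#' Write a panel to its JSON configuration format
#'
#' @param panel A validated `nmr_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  ss <- panel$spin_systems
  comp <- panel$components
  obj <- list(
    version = panel$version %||% PANEL_FORMAT_VERSION,
    ph_range = panel$ph_range,
    temp_levels_K = panel$temp_levels_K,
    components = lapply(seq_len(nrow(comp)), function(i) list(
      name = comp$name[i], role = comp$role[i],
      conc_range = c(comp$conc_min[i], comp$conc_max[i]),
      nmr_visible = comp$nmr_visible[i],
      spin_systems = comp$spin_systems[[i]])),
    spin_systems = lapply(seq_len(nrow(ss)), function(i) list(
      id = ss$id[i], metabolite = ss$metabolite[i],
      proton_label = ss$proton_label[i],
      multiplicity = ss$multiplicity[i], n_protons = ss$n_protons[i],
      j_hz = ss$j_hz[[i]], delta_free = ss$delta_free[i],
      window = c(ss$window_lo[i], ss$window_hi[i]),
      is_navigator = ss$is_navigator[i])))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' Built-in demonstration panel
#'
#' A reduced, desk-scale panel of 12 active metabolites (including the
#' navigator metabolites citrate, creatinine and glycine, plus histidine,
#' 3-methylhistidine, TMAO, hippurate, alanine, lactate, succinate, taurine
#' and formate), 2 passive metabolites (creatine, dimethylamine), 7
#' inorganic ions and albumin. Reference shifts are literature-typical
#' values and are configurable defaults, not measured ground truth; supply
#' your own panel file via [load_panel()] for other rosters. pH range is the
#' buffered 6.4-7.6 window and the acquisition temperatures are 300.0 and
#' 302.7 K.
#'
#' @return A validated `nmr_panel`.
#' @export
default_panel <- function() {
  mk_ss <- function(id, metabolite, label, mult, np, j, delta, win, nav) {
    list(id = id, metabolite = metabolite, proton_label = label,
         multiplicity = mult, n_protons = np, j_hz = j, delta_free = delta,
         window_lo = win[1], window_hi = win[2], is_navigator = nav)
  }
  ssl <- list(
    mk_ss("cit_h1",  "citrate",           "H3,6a", "dd", 2L, 15.9, 2.540,
          c(2.490, 2.600), TRUE),
    mk_ss("cit_h2",  "citrate",           "H3,6b", "dd", 2L, 15.9, 2.660,
          c(2.610, 2.710), TRUE),
    mk_ss("cre_h3",  "creatinine",        "H3",    "s",  3L, numeric(0), 3.045,
          c(3.000, 3.090), TRUE),
    mk_ss("cre_h7",  "creatinine",        "H7",    "s",  2L, numeric(0), 4.060,
          c(4.010, 4.110), TRUE),
    mk_ss("gly_h2",  "glycine",           "H2",    "s",  2L, numeric(0), 3.560,
          c(3.500, 3.620), TRUE),
    mk_ss("his_h5",  "histidine",         "H5",    "s",  1L, numeric(0), 7.800,
          c(7.680, 7.980), FALSE),
    mk_ss("mhis_h5", "3-methylhistidine", "H5",    "s",  1L, numeric(0), 7.620,
          c(7.540, 7.670), FALSE),
    mk_ss("tmao_h1", "TMAO",              "H1",    "s",  9L, numeric(0), 3.270,
          c(3.220, 3.320), FALSE),
    mk_ss("hip_h7",  "hippurate",         "H7",    "d",  2L, 5.9, 3.970,
          c(3.935, 4.000), FALSE),
    mk_ss("ala_h3",  "alanine",           "H3",    "d",  3L, 7.26, 1.480,
          c(1.440, 1.520), FALSE),
    mk_ss("lac_h3",  "lactate",           "H3",    "d",  3L, 6.94, 1.330,
          c(1.290, 1.370), FALSE),
    mk_ss("suc_h2",  "succinate",         "H2,3",  "s",  4L, numeric(0), 2.410,
          c(2.370, 2.450), FALSE),
    mk_ss("tau_h1",  "taurine",           "H1",    "t",  2L, 6.6, 3.420,
          c(3.370, 3.470), FALSE),
    mk_ss("for_h1",  "formate",           "H1",    "s",  1L, numeric(0), 8.450,
          c(8.400, 8.500), FALSE),
    mk_ss("crt_h2",  "creatine",          "H2",    "s",  2L, numeric(0), 3.930,
          c(3.900, 3.955), FALSE),
    mk_ss("dma_h1",  "dimethylamine",     "H1",    "s",  6L, numeric(0), 2.760,
          c(2.730, 2.790), FALSE))
  ss <- data.frame(
    id = vapply(ssl, `[[`, character(1), "id"),
    metabolite = vapply(ssl, `[[`, character(1), "metabolite"),
    proton_label = vapply(ssl, `[[`, character(1), "proton_label"),
    multiplicity = vapply(ssl, `[[`, character(1), "multiplicity"),
    n_protons = vapply(ssl, `[[`, integer(1), "n_protons"),
    delta_free = vapply(ssl, `[[`, numeric(1), "delta_free"),
    window_lo = vapply(ssl, `[[`, numeric(1), "window_lo"),
    window_hi = vapply(ssl, `[[`, numeric(1), "window_hi"),
    is_navigator = vapply(ssl, `[[`, logical(1), "is_navigator"),
    stringsAsFactors = FALSE)
  ss$j_hz <- lapply(ssl, `[[`, "j_hz")

  mk_c <- function(name, role, range, visible, systems) {
    list(name = name, role = role, conc_min = range[1], conc_max = range[2],
         nmr_visible = visible, spin_systems = systems)
  }
  cl <- list(
    mk_c("citrate",           "active_metabolite", c(500, 6000),    TRUE,
         c("cit_h1", "cit_h2")),
    mk_c("creatinine",        "active_metabolite", c(2400, 24000),  TRUE,
         c("cre_h3", "cre_h7")),
    mk_c("glycine",           "active_metabolite", c(300, 4000),    TRUE,
         "gly_h2"),
    mk_c("histidine",         "active_metabolite", c(100, 1300),    TRUE,
         "his_h5"),
    mk_c("3-methylhistidine", "active_metabolite", c(50, 600),      TRUE,
         "mhis_h5"),
    mk_c("TMAO",              "active_metabolite", c(200, 1500),    TRUE,
         "tmao_h1"),
    mk_c("hippurate",         "active_metabolite", c(200, 3500),    TRUE,
         "hip_h7"),
    mk_c("alanine",           "active_metabolite", c(100, 700),     TRUE,
         "ala_h3"),
    mk_c("lactate",           "active_metabolite", c(100, 1200),    TRUE,
         "lac_h3"),
    mk_c("succinate",         "active_metabolite", c(20, 300),      TRUE,
         "suc_h2"),
    mk_c("taurine",           "active_metabolite", c(200, 1600),    TRUE,
         "tau_h1"),
    mk_c("formate",           "active_metabolite", c(100, 600),     TRUE,
         "for_h1"),
    mk_c("creatine",          "passive_metabolite", c(50, 400),     TRUE,
         "crt_h2"),
    mk_c("dimethylamine",     "passive_metabolite", c(100, 600),    TRUE,
         "dma_h1"),
    mk_c("Na+",       "inorganic_ion", c(40000, 220000), FALSE, character(0)),
    mk_c("Cl-",       "inorganic_ion", c(40000, 240000), FALSE, character(0)),
    mk_c("K+",        "inorganic_ion", c(25000, 125000), FALSE, character(0)),
    mk_c("Ca2+",      "inorganic_ion", c(1000, 10000),   FALSE, character(0)),
    mk_c("Mg2+",      "inorganic_ion", c(1000, 8000),    FALSE, character(0)),
    mk_c("phosphate", "inorganic_ion", c(10000, 50000),  FALSE, character(0)),
    mk_c("sulfate",   "inorganic_ion", c(5000, 25000),   FALSE, character(0)),
    mk_c("albumin",   "protein",       c(0.2, 3.0),      FALSE, character(0)))
  comp <- data.frame(
    name = vapply(cl, `[[`, character(1), "name"),
    role = vapply(cl, `[[`, character(1), "role"),
    conc_min = vapply(cl, `[[`, numeric(1), "conc_min"),
    conc_max = vapply(cl, `[[`, numeric(1), "conc_max"),
    nmr_visible = vapply(cl, `[[`, logical(1), "nmr_visible"),
    stringsAsFactors = FALSE)
  comp$spin_systems <- lapply(cl, `[[`, "spin_systems")

  panel <- panel_new(comp, ss, c(6.4, 7.6), c(300.0, 302.7))
  validate_panel(panel)
  panel
}

# Convenience accessors -------------------------------------------------------

# Spin systems attached to active metabolites (the "active signals").
active_signal_ids <- function(panel) {
  comp <- panel$components
  act <- comp$name[comp$role == "active_metabolite"]
  ids <- unlist(comp$spin_systems[comp$name %in% act])
  panel$spin_systems$id[panel$spin_systems$id %in% ids]
}

navigator_ids <- function(panel) {
  panel$spin_systems$id[panel$spin_systems$is_navigator]
}

# Components whose concentrations the pipeline models (active metabolites,
# inorganic ions and protein; passive metabolites are shift reporters only).
modelled_component_names <- function(panel) {
  comp <- panel$components
  comp$name[comp$role %in% c("active_metabolite", "inorganic_ion", "protein")]
}

component_of_signal <- function(panel, id) {
  comp <- panel$components
  hit <- vapply(comp$spin_systems, function(x) id %in% x, logical(1))
  comp$name[hit][1]
}

#' @export
print.nmr_panel <- function(x, ...) {
  cat("NMR panel:", nrow(x$components), "components,",
      nrow(x$spin_systems), "spin systems",
      sprintf("(%d navigators)\n", sum(x$spin_systems$is_navigator)))
  cat(sprintf("  pH %.1f-%.1f, T levels: %s K\n", x$ph_range[1], x$ph_range[2],
              paste(x$temp_levels_K, collapse = ", ")))
  invisible(x)
}
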
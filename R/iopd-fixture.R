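#' Curated IOPD concept network
#'
#' A literature-anchored signed network of 53 concepts for simulating
#' reprogramming of fibroblasts to pluripotency, MyoD1-driven
#' transdifferentiation to skeletal muscle, and infantile-onset Pompe
#' disease (IOPD, GAA loss) phenotypes. It is a deliberately small
#' surrogate for the proprietary multi-thousand-concept databases used by
#' commercial qualitative simulators: it reproduces the directional
#' steady-state calls reported for such systems, not their scale or
#' iteration counts.
#'
#' Structure, by axis:
#' \itemize{
#'   \item Reprogramming: OSKM factors (OCT4/SOX2/KLF4/cMYC), Doxycycline,
#'     exogenous vs endogenous MyoD1, fibroblast context.
#'   \item Pluripotency: a mutually activating OCT4-SOX2-NANOG core (a
#'     bistable latch: a transient OSKM pulse switches it on and it then
#'     self-sustains) driving the embryonic-stem-cell marker panel (GDF3,
#'     REX1, FGF4, DPPA5, DPPA2, DPPA4, hTERT, SALL4, E-CADHERIN,
#'     SSEA-3/4, TRA-1-81, ALP).
#'   \item Muscle: MyoD1 -> Myogenin/CKM/MyHC with Pax7 repression;
#'     mutual antagonism between the pluripotency core and MyoD1 makes
#'     pluripotent and differentiated states exclusive attractors.
#'   \item Disease: GAA inhibits lysosomal glycogen accumulation; glycogen
#'     drives LAMP2, glucose deprivation and mTORC1 suppression (with
#'     p70S6K/p4EBP1 phosphorylation downstream), autophagy/mitophagy
#'     (LC3, p62, Pink2), mitochondrial dysfunction (ROS, CytC, AIF,
#'     Caspase3, apoptosis, cell death, DNM1L, MFN2, ADP up / ATP down)
#'     and the VDCC -> intracellular calcium -> calpain axis. Lysosomal
#'     calcium has only context drive, so it is genotype-invariant.
#' }
#'
#' Each relation carries a provenance note: `literature:` notes restate, in
#' this package's words, mechanisms reported for the wet-lab and simulated
#' IOPD models the network emulates; `curated: closure edge` marks edges we
#' added so signals propagate, with no direct literature anchor.
#' Deliberately absent (not modelled by the system this emulates):
#' TRA-1-60, Park2, FIS1, OPA1, COX4l1 and mitochondrial calcium.
#'
#' @return A [ConceptNetwork-class] with 53 concepts.
#' @examples
#' net <- iopdNetwork()
#' nConcepts(net)
#' subset(relations(net), source == "GAA")
#' @export
iopdNetwork <- function() {
  k <- function(ids, kind) data.frame(id = ids, kind = kind,
                                      stringsAsFactors = FALSE)
  co <- rbind(
    k(c("Fibroblast", "lysosomal_glycogen", "glucose_deprivation",
        "mitochondrial_dysfunction", "impaired_energy_metabolism",
        "apoptosis", "cell_death", "autophagy", "mitophagy"), "phenotype"),
    k(c("Doxycycline", "ATP", "ADP", "ROS", "intracellular_calcium",
        "lysosomal_calcium"), "compound"),
    k(c("MyoD1_exo", "MyoD1", "OCT4", "SOX2", "KLF4", "cMYC", "NANOG",
        "GDF3", "REX1", "FGF4", "DPPA5", "DPPA2", "DPPA4", "hTERT",
        "SALL4", "CKM", "Myogenin", "Pax7", "GAA"), "gene"),
    k(c("ECAD", "SSEA34", "TRA_1_81", "ALP", "MyHC", "LAMP2", "mTORC1_p",
        "p70S6K_p", "p4EBP1_p", "CytC", "AIF", "Caspase3", "DNM1L",
        "MFN2", "LC3", "p62", "Pink2", "VDCC", "calpain"), "protein"))
  co$label <- co$id
  co$aliases <- ""
  al <- c(MyoD1_exo = "exogenous MyoD1;MYOD1-transgene",
          MyoD1 = "MYOD1;MyoD1-endogenous",
          OCT4 = "OCT3/4;POU5F1", cMYC = "MYC;c-MYC",
          REX1 = "ZFP42", DPPA5 = "ESG1;ESG1/DPPA5", hTERT = "TERT",
          ECAD = "E-CADHERIN;CDH1", SSEA34 = "SSEA-3/4;SSEA3;SSEA4",
          TRA_1_81 = "TRA-1-81", ALP = "alkaline phosphatase",
          Myogenin = "MYOG", MyHC = "myosin heavy chain",
          mTORC1_p = "mTORC1-p;p-mTORC1", p70S6K_p = "p70S6K-p",
          p4EBP1_p = "p4EBP1-p", CytC = "Cytochrome C",
          LC3 = "LC3/LC3-II;LC3-II;LCII", p62 = "SQSTM1;p62(SQSTM1)",
          Doxycycline = "Dox")
  co$aliases[match(names(al), co$id)] <- unname(al)

  e <- function(source, target, weight, note) {
    data.frame(source = source, target = target, weight = weight,
               provenance = note, stringsAsFactors = FALSE)
  }
  lit <- function(s, t, w, what) e(s, t, w, paste0("literature: ", what))
  cur <- function(s, t, w) e(s, t, w, "curated: closure edge")

  core <- rbind(
    lit("OCT4", "NANOG", 0.8, "core pluripotency circuit"),
    lit("SOX2", "NANOG", 0.8, "core pluripotency circuit"),
    lit("KLF4", "NANOG", 0.3, "reprogramming factor input"),
    lit("cMYC", "NANOG", 0.3, "reprogramming factor input"),
    lit("NANOG", "OCT4", 0.8, "core pluripotency circuit"),
    lit("NANOG", "SOX2", 0.8, "core pluripotency circuit"),
    lit("OCT4", "SOX2", 0.4, "core pluripotency circuit"),
    lit("SOX2", "OCT4", 0.4, "core pluripotency circuit"),
    cur("NANOG", "KLF4", 0.4),
    cur("NANOG", "cMYC", 0.4))

  markers <- c("GDF3", "REX1", "FGF4", "DPPA5", "DPPA2", "DPPA4", "hTERT",
               "SALL4", "ECAD", "SSEA34", "TRA_1_81", "ALP")
  panel <- do.call(rbind, lapply(markers, function(mk) rbind(
    lit("NANOG", mk, 0.6, "undifferentiated ESC marker panel"),
    lit("OCT4", mk, 0.3, "undifferentiated ESC marker panel"))))

  muscle <- rbind(
    lit("MyoD1_exo", "MyoD1", 0.5, "transgene induces endogenous program"),
    cur("Doxycycline", "MyoD1", 0.2),
    cur("Myogenin", "MyoD1", 0.4),
    cur("NANOG", "MyoD1", -0.9),
    cur("OCT4", "MyoD1", -0.9),
    cur("MyoD1", "NANOG", -0.6),
    cur("MyoD1", "OCT4", -0.6),
    cur("MyoD1", "SOX2", -0.6),
    lit("MyoD1", "Myogenin", 0.8, "myogenic differentiation cascade"),
    lit("MyoD1", "CKM", 0.7, "mature skeletal muscle marker"),
    lit("Myogenin", "CKM", 0.5, "mature skeletal muscle marker"),
    lit("MyoD1", "MyHC", 0.7, "mature skeletal muscle marker"),
    lit("Myogenin", "MyHC", 0.5, "mature skeletal muscle marker"),
    cur("Fibroblast", "Pax7", 0.3),
    lit("MyoD1", "Pax7", -0.8,
        "Pax7 down-regulated on MyoD1-driven differentiation"),
    cur("Myogenin", "Pax7", -0.5))

  context <- rbind(
    cur("Fibroblast", "GAA", 0.15),
    cur("Fibroblast", "lysosomal_glycogen", 0.2),
    cur("Fibroblast", "mTORC1_p", 0.4),
    cur("Fibroblast", "ATP", 0.4),
    cur("Fibroblast", "lysosomal_calcium", 0.2),
    cur("Fibroblast", "LAMP2", 0.1),
    lit("Doxycycline", "mTORC1_p", 0.2,
        "tetracycline-class drugs act on PI3K-AKT-mTOR signalling"))

  disease <- rbind(
    lit("GAA", "lysosomal_glycogen", -1.0,
        "GAA converts lysosomal glycogen to glucose"),
    lit("lysosomal_glycogen", "LAMP2", 0.8,
        "lysosomal expansion marker rises with glycogen load"),
    lit("lysosomal_glycogen", "glucose_deprivation", 0.8,
        "sequestered glycogen starves the cytosol of glucose"),
    cur("GAA", "glucose_deprivation", -0.4),
    lit("lysosomal_glycogen", "mTORC1_p", -0.9,
        "mTORC1 activity suppressed with lysosomal glycogen accumulation"),
    lit("mTORC1_p", "p70S6K_p", 0.9, "direct mTORC1 substrate"),
    lit("mTORC1_p", "p4EBP1_p", 0.9, "direct mTORC1 substrate"),
    lit("mTORC1_p", "autophagy", -0.8, "mTORC1 represses autophagy"),
    lit("autophagy", "LC3", 0.8, "autophagosome marker"),
    lit("autophagy", "p62", 0.6,
        "receptor accumulates when flux is incomplete"),
    cur("lysosomal_glycogen", "p62", 0.3),
    lit("mitochondrial_dysfunction", "Pink2", 0.8,
        "mitophagy signalling on damaged mitochondria"),
    lit("Pink2", "mitophagy", 0.7, "mitophagy effector arm"),
    cur("autophagy", "mitophagy", 0.4),
    cur("glucose_deprivation", "VDCC", 0.7),
    cur("calpain", "VDCC", 0.3),
    lit("VDCC", "intracellular_calcium", 1.0,
        "calcium influx via VDCC-class channels"),
    lit("intracellular_calcium", "calpain", 0.9,
        "calcium-activated protease"),
    lit("calpain", "cell_death", 0.8, "calpain overactivation is cytotoxic"),
    lit("calpain", "mitochondrial_dysfunction", 0.7,
        "calcium/calpain overload injures mitochondria"),
    cur("lysosomal_glycogen", "mitochondrial_dysfunction", 0.3),
    cur("glucose_deprivation", "mitochondrial_dysfunction", 0.3),
    lit("mitochondrial_dysfunction", "ROS", 0.8,
        "dysfunction raises reactive oxygen species"),
    lit("mitochondrial_dysfunction", "CytC", 0.8,
        "Cytochrome C release from damaged mitochondria"),
    lit("mitochondrial_dysfunction", "AIF", 0.8,
        "apoptosis-inducing factor release"),
    lit("mitochondrial_dysfunction", "ADP", 0.9,
        "ADP markedly elevated under impaired respiration"),
    lit("mitochondrial_dysfunction", "ATP", -0.9, "reduced ATP generation"),
    lit("mitochondrial_dysfunction", "impaired_energy_metabolism", 0.9,
        "energy metabolism impaired as a dysfunction subnetwork"),
    lit("mitochondrial_dysfunction", "DNM1L", 0.7,
        "mitochondrial shaping protein elevated in disease"),
    lit("mitochondrial_dysfunction", "MFN2", 0.7,
        "mitochondrial shaping protein elevated in disease"),
    lit("CytC", "Caspase3", 0.8, "intrinsic apoptosis pathway"),
    cur("AIF", "Caspase3", 0.3),
    lit("Caspase3", "apoptosis", 0.9, "executioner caspase"),
    lit("apoptosis", "cell_death", 0.4, "apoptotic death route"),
    cur("glucose_deprivation", "impaired_energy_metabolism", 0.3))

  conceptNetwork(rbind(core, panel, muscle, context, disease),
                 concepts = co[, c("id", "label", "kind", "aliases")])
}
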
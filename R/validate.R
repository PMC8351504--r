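# Structural shape validation. The ontology ships no formal shapes; these
# rules are the mandatory patterns of the five canned queries, so a dataset
# that validates cleanly is guaranteed to be fully queryable. Patterns the
# queries wrap in OPTIONAL (tissue, cell line, taxon, organism name) are
# deliberately exempt, as is a saccharide part without any site mapping
# (partially missing site information must be representable).

.rule_messages <- c(
  R1 = "protein part lacks gco:has_protein",
  R2 = "protein lacks rdfs:seeAlso -> dcterms:identifier chain",
  R3 = "glycosylation region lacks faldo:location -> faldo:position >= 1 chain",
  R4 = "saccharide lacks foaf:primaryTopicOf -> GlyTouCan dcterms:identifier chain",
  R5 = "disease node lacks rdfs:label and/or skos:notation",
  R6 = "citation lacks glycan:has_pmid and/or dcterms:references",
  R7 = "referenced glycoconjugate has neither protein nor lipid part"
)

#' Validate a dataset against the GlycoCoO query shapes
#'
#' Applies seven structural rules per named graph:
#' \describe{
#'   \item{R1}{every `gco:has_protein_part` object has `gco:has_protein`.}
#'   \item{R2}{every protein reaches a `dcterms:identifier` via
#'     `rdfs:seeAlso`.}
#'   \item{R3}{every `gco:glycosylated_at` region chains `faldo:location` to
#'     a `faldo:position` integer >= 1.}
#'   \item{R4}{every `glycan:has_glycan` saccharide reaches, via
#'     `foaf:primaryTopicOf`, a `dcterms:identifier` matching the GlyTouCan
#'     pattern.}
#'   \item{R5}{every `sio:SIO_000628` disease carries `rdfs:label` and
#'     `skos:notation`.}
#'   \item{R6}{every `glycan:published_in` citation carries `glycan:has_pmid`
#'     and `dcterms:references`.}
#'   \item{R7}{every `gco:ReferencedGlycoconjugate` has at least one protein
#'     or lipid part.}
#' }
#' Problems are reported, never thrown; all rules are errors (no warning
#' tier), so `conforms` is TRUE exactly when `violations` is empty.
#'
#' @param ds a `glyco_dataset`.
#' @return object of class `glyco_validation`: list with `conforms` (logical)
#'   and `violations` (data.frame with columns `rule_id`, `graph`, `node`,
#'   `message`).
#' @export
#' @examples
#' validate_dataset(fixture_worked_example())$conforms
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "glyco_dataset"))
  q <- dataset_quads(ds)
  out <- list()

  obj_of <- function(qg, pred) unique(qg$object[qg$predicate == .p(pred)])
  subj_with <- function(qg, pred) qg$subject[qg$predicate == .p(pred)]

  for (g in unique(q$graph)) {
    qg <- q[q$graph == g, , drop = FALSE]
    viol <- function(rule, nodes) {
      if (length(nodes) == 0L) return(NULL)
      data.frame(rule_id = rule, graph = if (g == "") "" else term_str(g),
                 node = term_str(nodes),
                 message = unname(.rule_messages[rule]),
                 stringsAsFactors = FALSE)
    }

    # R1: protein parts must name their protein
    parts <- obj_of(qg, "gco:has_protein_part")
    out[[length(out) + 1L]] <-
      viol("R1", parts[!(parts %in% subj_with(qg, "gco:has_protein"))])

    # R2: protein -> seeAlso -> identifier
    proteins <- obj_of(qg, "gco:has_protein")
    see <- qg[qg$predicate == .p("rdfs:seeAlso"), , drop = FALSE]
    idents <- subj_with(qg, "dcterms:identifier")
    ok_protein <- unique(see$subject[see$object %in% idents])
    out[[length(out) + 1L]] <- viol("R2", proteins[!(proteins %in% ok_protein)])

    # R3: region -> location -> position (integer >= 1)
    regions <- obj_of(qg, "gco:glycosylated_at")
    locs <- qg[qg$predicate == .p("faldo:location"), , drop = FALSE]
    posq <- qg[qg$predicate == .p("faldo:position"), , drop = FALSE]
    pos_ok_nodes <- posq$subject[!is.na(term_numeric(posq$object)) &
                                   term_numeric(posq$object) >= 1]
    ok_region <- unique(locs$subject[locs$object %in% pos_ok_nodes])
    out[[length(out) + 1L]] <- viol("R3", regions[!(regions %in% ok_region)])

    # R4: saccharide -> primaryTopicOf -> GlyTouCan identifier
    sacs <- obj_of(qg, "glycan:has_glycan")
    topics <- qg[qg$predicate == .p("foaf:primaryTopicOf"), , drop = FALSE]
    idq <- qg[qg$predicate == .p("dcterms:identifier"), , drop = FALSE]
    gtc_xrefs <- idq$subject[is_glytoucan_accession(term_str(idq$object))]
    ok_sac <- unique(topics$subject[topics$object %in% gtc_xrefs])
    out[[length(out) + 1L]] <- viol("R4", sacs[!(sacs %in% ok_sac)])

    # R5: disease nodes need label and notation
    diseases <- obj_of(qg, "sio:SIO_000628")
    has_lab <- diseases %in% subj_with(qg, "rdfs:label")
    has_not <- diseases %in% subj_with(qg, "skos:notation")
    out[[length(out) + 1L]] <- viol("R5", diseases[!(has_lab & has_not)])

    # R6: citations need has_pmid and dcterms:references
    cits <- obj_of(qg, "glycan:published_in")
    has_pmid <- cits %in% subj_with(qg, "glycan:has_pmid")
    has_ref <- cits %in% subj_with(qg, "dcterms:references")
    out[[length(out) + 1L]] <- viol("R6", cits[!(has_pmid & has_ref)])

    # R7: conjugates need a protein or lipid part
    conjs <- qg$subject[qg$predicate == .p("rdf:type") &
                          qg$object == .p("gco:ReferencedGlycoconjugate")]
    has_part <- conjs %in% subj_with(qg, "gco:has_protein_part") |
      conjs %in% subj_with(qg, "gcx:has_lipid_part")
    out[[length(out) + 1L]] <- viol("R7", unique(conjs[!has_part]))
  }

  violations <- do.call(rbind, c(out, list(
    data.frame(rule_id = character(0), graph = character(0),
               node = character(0), message = character(0),
               stringsAsFactors = FALSE))))
  violations <- violations[order(violations$graph, violations$rule_id,
                                 violations$node, method = "radix"), ,
                           drop = FALSE]
  rownames(violations) <- NULL
  structure(list(conforms = nrow(violations) == 0L, violations = violations),
            class = "glyco_validation")
}

#' @export
print.glyco_validation <- function(x, ...) {
  if (x$conforms) {
    cat("conforms: TRUE (0 violations)\n")
  } else {
    cat(sprintf("conforms: FALSE (%d violation(s))\n", nrow(x$violations)))
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}
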
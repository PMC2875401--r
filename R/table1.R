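# Machine-readable copy of the fosmid gene table (fosmids 7-14 and 7-25).
# One row per annotated feature; coordinates are 1-based inclusive on the
# cloned insert. lgt_nj / lgt_ml hold the per-method assessments (the printed
# table lists the NJ assessment first and, when the ML assessment differs, in
# parentheses). `direction`, when resolved, names donor and recipient groups.
# top_focal records whether the top BLASTX hit species belongs to the focal
# group (cluster IV); top_group is a curated cluster placement per species.
.table1_text <- "fosmid\tcds\tstart\tend\tstrand\tgc\tfunc\tfeature_class\tmobile_element\tlgt_nj\tlgt_ml\tdirection\ttop_species\ttop_accession\ttop_evalue\ttop_pid\ttop_focal\ttop_group
7-14\t1\t18\t920\t+\t53.0\tTransposase for insertion sequence element ISRM5\tprotein_coding\tTRUE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02038860\t2.00E-136\t92\tTRUE\tcluster_IV
7-14\t2\t1459\t1929\t-\t35.6\tTeicoplanin resistance protein vanZ\tprotein_coding\tFALSE\tnovel\tnovel\tnone\tGeobacillus thermodenitrificans\tYP_001124564\t7.00E-06\t31\tFALSE\tother
7-14\t3\t2346\t3584\t-\t50.8\tPutative transposase\tprotein_coding\tTRUE\tlgt\tlgt\tfrom_cluster_XIVa_to_cluster_IV\tCoprococcus eutactus\tZP_02205788\t2.00E-167\t69\tFALSE\tcluster_XIVa
7-14\t4\t4214\t5032\t-\t43.8\tHypothetical protein\tprotein_coding\tFALSE\tnovel\tnovel\tnone\tAnaerostipes caccae\tZP_02418355\t1.00E-03\t39\tFALSE\tcluster_XIVa
7-14\t5\t6252\t6962\t-\t51.9\tOuter membrane lipoprotein-sorting protein\tprotein_coding\tFALSE\tnovel\tnovel\tnone\tCaldicellulosiruptor saccharolyticus\tYP_001179297\t8.00E-06\t31\tFALSE\tother
7-14\t6\t6959\t7480\t-\t47.3\tRNA polymerase sigma-54 factor rpoN\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tAlkaliphilus oremlandii\tYP_001512203\t1.00E-28\t40\tFALSE\tother
7-14\t7\t7745\t7820\tnone\t63.2\ttRNA-Pro (TGG)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-14\t8\t8265\t10187\t-\t57.9\tLarge exoproteins involved in heme utilization or adhesion\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tHerpetosiphon aurantiacus\tYP_001545021\t2.00E-58\t35\tFALSE\tother
7-14\t9\t10188\t10862\t-\t55.4\tHypothetical protein\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tAnaerotruncus colihominis\tZP_02440985\t3.00E-38\t56\tTRUE\tcluster_IV
7-14\t10\t10855\t11580\t-\t54.4\tHypothetical protein\tprotein_coding\tFALSE\tlgt\tlgt\tunresolved\tDesulfitobacterium hafniense\tYP_517449\t7.00E-67\t56\tFALSE\tother
7-14\t11\t11732\t12193\t-\t52.8\tIron-sulfur cluster regulator IscR\tprotein_coding\tFALSE\tunresolved\tno_lgt\tnone\tAnaerotruncus colihominis\tZP_02443971\t2.00E-44\t65\tTRUE\tcluster_IV
7-14\t12\t12428\t13360\t+\t59.1\tCysteine synthase\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tFaecalibacterium prausnitzii\tZP_02090920\t4.00E-123\t83\tTRUE\tcluster_IV
7-14\t13\t13706\t13840\t-\t46.7\tSodium/glutamate symporter\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tEubacterium siraeum\tZP_02423775\t5.00E-12\t80\tTRUE\tcluster_IV
7-14\t14\t13795\t14877\t-\t56.7\tSodium/glutamate symporter\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tEubacterium siraeum\tZP_02423775\t7.00E-134\t73\tTRUE\tcluster_IV
7-14\t15\t14895\t15938\t-\t61.3\tImmunogenic protein\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tCoprococcus eutactus\tZP_02205701\t6.00E-61\t44\tFALSE\tcluster_XIVa
7-14\t16\t16214\t17023\t-\t57.9\t8-oxoguanine-DNA-glycosylase\tprotein_coding\tFALSE\tlgt\tlgt\tfrom_cluster_XIVa_to_cluster_IV\tRuminococcus torques\tZP_01966859\t9.00E-55\t43\tFALSE\tcluster_XIVa
7-14\t17\t17025\t18026\t-\t57.6\tL-asparaginase\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tClostridium bolteae\tZP_02087774\t7.00E-103\t54\tFALSE\tcluster_XIVa
7-14\t18\t18036\t19133\t-\t62.6\tExonuclease SbcD\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02034908\t3.00E-98\t55\tTRUE\tcluster_IV
7-14\t19\t19130\t19684\t-\t56.8\tEBSC protein\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tClostridium leptum\tZP_02078782\t2.00E-54\t68\tTRUE\tcluster_IV
7-14\t20\t19651\t20424\t-\t55.9\tPhosphoesterase family protein\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02034909\t4.00E-87\t61\tTRUE\tcluster_IV
7-14\t21\t21133\t21414\t-\t50.7\tHypothetical protein\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tEubacterium siraeum\tZP_02423392\t2.00E-08\t35\tTRUE\tcluster_IV
7-14\t22\t22289\t23032\t+\t54.6\tTransposase for insertion sequence element ISRM5\tprotein_coding\tTRUE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02038860\t1.00E-110\t87\tTRUE\tcluster_IV
7-14\t23\t23434\t23508\tnone\t58.7\ttRNA-Glu (CTC)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-14\t24\t23684\t23759\tnone\t52.6\ttRNA-Lys (CTT)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-14\t25\t23856\t26709\tnone\t52.5\t23S rRNA gene\trRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-14\t26\t27033\t27109\tnone\t63.6\ttRNA-Ile (GAT)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-14\t27\t27121\t27196\tnone\t53.9\ttRNA-Ala (TGC)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-14\t28\t27324\t28847\tnone\t53.5\t16S rRNA gene\trRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-14\t29\t29448\t30365\t-\t57.4\tGermination and sporulation\tprotein_coding\tFALSE\tlgt\tno_lgt\tfrom_cluster_XIVa_to_cluster_IV\tPseudoflavonifractor capillosus\tZP_02038021\t1.00E-25\t38\tTRUE\tcluster_IV
7-14\t30\t30362\t31768\t-\t60.5\tOsmosensitive K+ channel histidine kinase kdpD\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02038022\t1.00E-120\t52\tTRUE\tcluster_IV
7-14\t31\t31788\t32465\t-\t55.8\tTwo-component response regulator SA14-24\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02036840\t7.00E-86\t76\tTRUE\tcluster_IV
7-14\t32\t32486\t32854\t-\t55.3\tLate competence protein comEA, DNA receptor\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tCandidatus Desulforudis audaxviator\tYP_001718193\t3.00E-15\t58\tFALSE\tother
7-14\t33\t33191\t34558\t+\t57.1\tD-alanyl-D-alanine carboxypeptidase\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02036838\t3.00E-07\t47\tTRUE\tcluster_IV
7-14\t34\t34607\t35155\t-\t59.7\tNitroreductase family protein\tprotein_coding\tFALSE\tunresolved\tlgt\tfrom_cluster_XIVa_to_cluster_IV\tClostridium kluyveri\tYP_001393744\t9.00E-36\t50\tFALSE\tcluster_I
7-25\t1\t1\t794\t+\t51.5\tIntegrase\tprotein_coding\tTRUE\tlgt\tlgt\tfrom_cluster_XIVa_to_cluster_IV\tClostridium bolteae\tZP_02083674\t6.00E-90\t62\tFALSE\tcluster_XIVa
7-25\t2\t910\t2469\t-\t57.8\tGMP synthase [glutamine-hydrolyzing]\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02035344\t0.00E+00\t82\tTRUE\tcluster_IV
7-25\t3\t2447\t2962\t-\t56.2\tXanthine phosphoribosyltransferase\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tCoprococcus eutactus\tZP_02207218\t3.00E-43\t54\tFALSE\tcluster_XIVa
7-25\t4\t3418\t4239\t-\t60.5\tNucleotide-binding protein\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tEubacterium siraeum\tZP_02421312\t4.00E-91\t64\tTRUE\tcluster_IV
7-25\t5\t4308\t6572\t-\t61.3\tChromosome partition protein smc\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02034907\t6.00E-103\t35\tTRUE\tcluster_IV
7-25\t6\t7160\t8682\tnone\t53.6\t16S rRNA gene\trRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t7\t8810\t8885\tnone\t55.3\ttRNA-Ala (TGC)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t8\t8897\t8973\tnone\t64.9\ttRNA-Ile (GAT)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t9\t9297\t12150\tnone\t52.5\t23S rRNA gene\trRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t10\t12247\t12322\tnone\t53.9\ttRNA-Lys (CTT)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t11\t12498\t12572\tnone\t58.7\ttRNA-Glu (CTC)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t12\t12864\t12939\tnone\t57.9\ttRNA-Asn (GTT)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t13\t12994\t13070\tnone\t61.0\ttRNA-Met (CAT)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t14\t13108\t13183\tnone\t59.2\ttRNA-Trp (CCA)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t15\t13246\t13322\tnone\t62.3\ttRNA-Asp (GTC)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t16\t13328\t13403\tnone\t59.2\ttRNA-Thr (GGT)\ttRNA\tFALSE\tnot_applicable\tnot_applicable\tnot_applicable\t\t\t\t\tNA\t
7-25\t17\t13613\t14674\t+\t54.3\tTransposase for insertion sequence element ISRM5\tprotein_coding\tTRUE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02038860\t4.00E-131\t89\tTRUE\tcluster_IV
7-25\t18\t15027\t15791\t+\t40.4\tUnknown\tprotein_coding\tFALSE\tunresolved\tno_lgt\tnone\tBacteroides thetaiotaomicron\tNP_810500\t1.00E-117\t78\tFALSE\tother
7-25\t19\t15913\t17193\t+\t55.2\tHypothetical protein\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tEubacterium siraeum\tZP_02421339\t4.00E-86\t44\tTRUE\tcluster_IV
7-25\t20\t17144\t18088\t+\t56.9\tHypothetical protein\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tEubacterium ventriosum\tZP_02027484\t5.00E-66\t43\tFALSE\tcluster_XIVa
7-25\t21\t18370\t19662\t+\t58.0\tPutative stomatin/prohibitin-family membrane protease subunit\tprotein_coding\tFALSE\tlgt\tlgt\tunresolved\tClostridium acetobutylicum\tNP_349972\t2.00E-92\t48\tFALSE\tcluster_I
7-25\t22\t19560\t20867\t+\t57.0\tProtein RtcB\tprotein_coding\tFALSE\tno_lgt\tno_lgt\tnone\tPseudoflavonifractor capillosus\tZP_02038919\t2.00E-154\t69\tTRUE\tcluster_IV
7-25\t23\t20864\t21208\t+\t55.1\tPredicted nucleotidyltransferase\tprotein_coding\tFALSE\tunresolved\tunresolved\tnone\tEscherichia coli\tZP_03048733\t5.00E-16\t59\tFALSE\tother
7-25\t24\t22686\t23951\t+\t53.7\tHypothetical lipoprotein\tprotein_coding\tFALSE\tlgt\tlgt\tfrom_cluster_XIVa_to_cluster_IV\tClostridium bolteae\tZP_02087827\t0.00E+00\t82\tFALSE\tcluster_XIVa
7-25\t25\t24010\t25620\t+\t48.6\tABC-type sugar transport system, ATP-binding protein\tprotein_coding\tFALSE\tlgt\tlgt\tfrom_cluster_XIVa_to_cluster_IV\tClostridium bolteae\tZP_02087828\t0.00E+00\t89\tFALSE\tcluster_XIVa
7-25\t26\t25634\t26713\t+\t54.8\tABC transporter integral membrane protein\tprotein_coding\tFALSE\tlgt\tlgt\tfrom_cluster_XIVa_to_cluster_IV\tClostridium bolteae\tZP_02087829\t2.00E-164\t88\tFALSE\tcluster_XIVa
7-25\t27\t26710\t27834\t+\t54.3\tABC transporter integral membrane protein\tprotein_coding\tFALSE\tlgt\tlgt\tfrom_cluster_XIVa_to_cluster_IV\tClostridium bolteae\tZP_02087830\t7.00E-167\t84\tFALSE\tcluster_XIVa
7-25\t28\t27831\t28319\t+\t54.6\tHypothetical protein\tprotein_coding\tFALSE\tlgt\tlgt\tunresolved\tClostridium bolteae\tZP_02087831\t6.00E-47\t70\tFALSE\tcluster_XIVa"

lgt_status_vocabulary <- function() {
  c("no_lgt", "novel", "unresolved", "lgt", "not_applicable")
}

.table1_data <- function() {
  df <- read.delim(text = .table1_text, stringsAsFactors = FALSE,
                   colClasses = list(fosmid = "character"))
  df$top_evalue <- suppressWarnings(as.numeric(df$top_evalue))
  df
}

#' Re-emit the packaged fosmid gene-table fixture
#'
#' Writes the embedded machine-readable gene table to `path`, byte-identical
#' to the copy shipped under `inst/extdata/table1_cds.tsv`. Having both an
#' embedded literal and a packaged file lets the loader and the fixture be
#' tested against each other.
#'
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table1_fixture <- function(path) {
  writeLines(.table1_text, path, useBytes = TRUE)
  invisible(path)
}

#' Load the fosmid gene-table fixture
#'
#' Reads the packaged table of annotated features on fosmids 7-14 and 7-25
#' (or a user copy) and validates its frozen invariants: 62 rows in total,
#' 44 protein-coding CDS and 18 RNA-operon features (two 16S, two 23S,
#' fourteen tRNA genes); coordinates with start < end; GC in \[0, 100\];
#' LGT-assessment vocabulary respected, with RNA features marked
#' not-applicable.
#'
#' @param path Path to a fixture TSV; defaults to the packaged copy.
#' @return A data.frame of CDS records (one row per feature).
#' @export
#' @examples
#' tab <- load_table1_fixture()
#' table(tab$feature_class)
load_table1_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_cds.tsv", package = "lgtree",
                        mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(fosmid = "character"))
  df$top_evalue <- suppressWarnings(as.numeric(df$top_evalue))

  fail <- function(msg) abort_lgtree(paste0("fixture integrity: ", msg),
                                     "lgtree_fixture_error")
  if (nrow(df) != 62) fail(sprintf("expected 62 rows, found %d", nrow(df)))
  if (sum(df$fosmid == "7-14") != 34 || sum(df$fosmid == "7-25") != 28)
    fail("per-fosmid row counts must be 34 (7-14) and 28 (7-25)")
  cls <- table(df$feature_class)
  if (cls[["protein_coding"]] != 44) fail("expected 44 protein-coding rows")
  if (cls[["rRNA"]] != 4 || cls[["tRNA"]] != 14)
    fail("expected 4 rRNA and 14 tRNA rows")
  if (sum(grepl("16S", df$func)) != 2 || sum(grepl("23S", df$func)) != 2)
    fail("expected two 16S and two 23S genes")
  if (any(df$start >= df$end)) fail("start must be < end")
  if (any(df$gc < 0 | df$gc > 100)) fail("GC percent outside [0, 100]")
  if (!all(df$strand %in% c("+", "-", "none"))) fail("bad strand value")
  vocab <- lgt_status_vocabulary()
  if (!all(df$lgt_nj %in% vocab) || !all(df$lgt_ml %in% vocab))
    fail("LGT assessment outside vocabulary")
  rna <- df$feature_class %in% c("rRNA", "tRNA")
  if (!all(df$lgt_nj[rna] == "not_applicable" &
           df$lgt_ml[rna] == "not_applicable"))
    fail("RNA features must carry not_applicable LGT assessments")
  df
}

#' 1-based inclusive to 0-based half-open coordinates
#'
#' Boundary converter for interchange with BED-style tooling; the fixture and
#' all in-package coordinates stay 1-based inclusive.
#'
#' @param start,end Integer vectors, 1-based inclusive.
#' @return A data.frame with `start0` and `end0` columns.
#' @export
to_zero_based <- function(start, end) {
  data.frame(start0 = as.integer(start) - 1L, end0 = as.integer(end))
}
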
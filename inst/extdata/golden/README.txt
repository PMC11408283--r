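Hand-checkable curation fixture (synthetic, constructed by hand).

12 records over 7 compounds and 2 proteins exercise every curation rule:
 - C1|P1: two sources, 5 and 8 uM -> positive, representative = min = 5 uM.
 - C2|P1: potent (2 uM) but MW 50 Da -> compound removed by the 100-1000 Da
   window; the pair never resolves.
 - C3|P1 and C4|P1: both positive, Tanimoto(C3, C4) = 9/11 ~ 0.818 > 0.8 on
   the same protein; C4 participates in 2 resolved pairs vs 1 for C3, so the
   ligand-bias rule keeps C4|P1 and discards C3|P1.
 - C5|P1: exactly 10 uM -> positive (inclusive threshold); MW exactly 1000 Da
   -> retained (inclusive window).
 - C6|P1: 15 uM and 20000 nM (= 20 uM after unit normalization) -> negative,
   representative = 15 uM.
 - C1|P2: 20 uM (negative evidence) plus a binary "active" record -> positive
   by the any-active rule; representative stays 20 uM.
 - C7|P1: 12 uM -> negative.
Result: 7 resolved pairs, 5 positive, 2 negative (expected-pairs.tsv).
Re-running with negatives_cap_per_protein = 1 keeps only C6|P1 of P1's two
negatives (equal interaction counts; lexicographic tie-break).
Fingerprints use bit positions within 1..64 (use nbits = 64).
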
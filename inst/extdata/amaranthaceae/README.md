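# Amaranthaceae rbcL data (not distributed)

The published rbcL dataset this package's full-scale analyses target is
distributed as supplementary material of its original study and is not
redistributed here. To run the data-dependent acceptance checks and the
integration reproduction (`inst/scripts/reproduce_amaranthaceae.R`), place
three files in this directory:

- `rbcL_alignment.fasta` — 179 aligned rbcL coding sequences, 1341 nt
  (codon positions corresponding to residues 22-468).
- `rbcL_tree.nwk` — the phylogeny of the same 179 taxa, Newick, branch
  lengths required; bootstrap labels are tolerated.
- `phenotypes.tsv` — two tab-separated columns, no header:
  taxon name, photosynthetic type (`C3` or `C4`); 95 C3 and 84 C4 taxa.

Expected deterministic properties once present: a 179 x 447 codon matrix;
two-condition branch census {C4: 152, C3: 203}; three-condition census
{C3: 158, C4: 153}.
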
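Two acceptance tests reproduce published clade-level numbers from a
deposited supplementary dataset (98 taxa x 366 characters) that cannot be
redistributed with the package.  To run those reproductions, place the
deposited files in this directory under deposited/ with the names:

  deposited/matrix.nex        the 98 x 366 NEXUS character matrix
  deposited/mcc_tree.nex      the dated MCC tree with [&rate=...] annotations
  deposited/changes_tree.nex  the undated tree with change-unit branch lengths
  deposited/metadata.csv      taxon,clade,size_category table

Without them the two tests report failure with an explanatory message.
Everything else in the package runs on synthetic data generated in code.
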
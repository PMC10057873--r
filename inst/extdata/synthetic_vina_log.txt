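#################################################################
# Synthetic docking log fixture in the standard result-block    #
# format of AutoDock Vina style tools. Energies are the         #
# published rescoring values for the GW9662 control pose plus   #
# made-up lower-ranked modes; no docking run produced this file.#
#################################################################

Detected 1 CPU
Reading input ... done.
Setting up the scoring function ... done.
Analyzing the binding site ... done.
Performing search ... done.
Refining results ... done.

mode |   affinity | dist from best mode
     | (kcal/mol) | rmsd l.b.| rmsd u.b.
-----+------------+----------+----------
   1         -7.98      0.000      0.000
   2         -7.41      1.822      2.590
   3         -7.02      2.114      3.336
   4         -6.85      2.908      4.880
   5         -6.51      3.190      5.104
   6         -6.20      3.771      6.012
   7         -5.94      4.102      6.733
   8         -5.61      4.455      7.208
   9         -5.32      5.016      7.991

Writing output ... done.
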
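# Ecosystem-conservation scenario edits, applied in order to the
# business-as-usual 2030 matrix:
# 1. conifer-to-broadleaf conversion probability increased by 50%
# 2. mountain/heath/bog persistence increased by 50%
# 3. broadleaf forest never converts to any other class
scale_cell conifer_forest broadleaf_forest 1.5 donor=diagonal
scale_diagonal mountain_heath_and_bog 1.5 donor=largest_offdiagonal
fix_row_identity broadleaf_forest
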
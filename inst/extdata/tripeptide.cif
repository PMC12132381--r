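data_tripeptide
#
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1 N N . LYS A 1 1 ? 0.000 0.000 0.000 1.00 10.00 1 LYS A N 1
ATOM 2 C CA . LYS A 1 1 ? 1.458 0.000 0.000 1.00 10.00 1 LYS A CA 1
ATOM 3 C C . LYS A 1 1 ? 2.009 1.420 0.000 1.00 10.00 1 LYS A C 1
ATOM 4 O O . LYS A 1 1 ? 1.251 2.390 0.000 1.00 10.00 1 LYS A O 1
ATOM 5 C CB . LYS A 1 1 ? 1.986 -0.773 -1.215 1.00 10.00 1 LYS A CB 1
ATOM 6 C CG . LYS A 1 1 ? 3.504 -0.888 -1.265 1.00 10.00 1 LYS A CG 1
ATOM 7 C CD . LYS A 1 1 ? 3.998 -1.681 -2.466 1.00 10.00 1 LYS A CD 1
ATOM 8 C CE . LYS A 1 1 ? 5.515 -1.796 -2.516 1.00 10.00 1 LYS A CE 1
ATOM 9 N NZ . LYS A 1 1 ? 6.009 -2.588 -3.717 1.00 10.00 1 LYS A NZ 1
ATOM 10 N N . GLY A 1 2 ? 3.332 1.536 0.000 1.00 10.00 2 GLY A N 1
ATOM 11 C CA . GLY A 1 2 ? 3.982 2.839 0.000 1.00 10.00 2 GLY A CA 1
ATOM 12 C C . GLY A 1 2 ? 5.496 2.719 0.000 1.00 10.00 2 GLY A C 1
ATOM 13 O O . GLY A 1 2 ? 6.041 1.613 0.000 1.00 10.00 2 GLY A O 1
ATOM 14 N N . GLU A 1 3 ? 6.193 3.851 0.000 1.00 10.00 3 GLU A N 1
ATOM 15 C CA . GLU A 1 3 ? 7.651 3.851 0.000 1.00 10.00 3 GLU A CA 1
ATOM 16 C C . GLU A 1 3 ? 8.202 5.271 0.000 1.00 10.00 3 GLU A C 1
ATOM 17 O O . GLU A 1 3 ? 7.444 6.241 0.000 1.00 10.00 3 GLU A O 1
ATOM 18 C CB . GLU A 1 3 ? 8.179 3.078 -1.215 1.00 10.00 3 GLU A CB 1
ATOM 19 C CG . GLU A 1 3 ? 9.697 2.963 -1.265 1.00 10.00 3 GLU A CG 1
ATOM 20 C CD . GLU A 1 3 ? 10.191 2.170 -2.466 1.00 10.00 3 GLU A CD 1
ATOM 21 O OE1 . GLU A 1 3 ? 9.414 1.604 -3.241 1.00 10.00 3 GLU A OE1 1
ATOM 22 O OE2 . GLU A 1 3 ? 11.428 2.093 -2.601 1.00 10.00 3 GLU A OE2 1
#
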
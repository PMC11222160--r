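data_fixture
# synthetic fixture: same model as fixture_model.pdb
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
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1 P P . POP L 1 1 ? 1.500 2.500 3.500 1.00 0.00 ? 1 POP L P 1
ATOM 2 P P . POP L 1 2 ? -4.250 0.000 3.500 1.00 0.00 ? 2 POP L P 1
ATOM 3 P P . POP L 1 3 ? 6.000 -3.250 3.500 1.00 0.00 ? 3 POP L P 1
ATOM 4 C C1 . POP L 1 2 ? -4.250 0.000 -1.500 1.00 0.00 ? 2 POP L C1 1
HETATM 5 O O1 . Q1C Q 2 4 ? 0.000 0.000 23.500 1.00 0.00 ? 4 Q1C Q O1 1
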
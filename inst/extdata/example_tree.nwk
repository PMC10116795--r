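(((otu14:0.1450064464,((otu11:0.05797353546,otu1:0.05797353546):0.06843312402,(otu10:0.06261327119,(otu7:0.02324076,otu5:0.02324076):0.03937251119):0.06379338828):0.01859978697):0.1206219498,(otu12:0.1372813798,otu13:0.1372813798):0.1283470165):4.223610504,(((otu4:0.01648215783,otu8:0.01648215783):0.1131659639,(((otu2:0.0390473829,otu3:0.0390473829):0.01521340075,otu9:0.05426078365):0.07178702481,otu6:0.1260478085):0.003600313245):0.08325444437,otu15:0.2129025661):4.276336334);
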
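sample,name,code,percentage,sd,lipid_content
Ano,Caproic acid,C6:0,N.D.,,9.92
Ano,Capric acid,C10:0,N.D.,,9.92
Ano,Lauric acid,C12:0,N.D.,,9.92
Ano,Myristic acid,C14:0,1.72,0.01,9.92
Ano,Pentadecanoic acid,C15:0,0.55,0.04,9.92
Ano,Palmitic acid,C16:0,33.02,0.01,9.92
Ano,Margaric acid,C17:0,0.38,0.01,9.92
Ano,Stearic acid,C18:0,5.63,0.02,9.92
Ano,Behenic acid,C22:0,0.23,0.02,9.92
Ano,Lignoceric acid,C24:0,0.22,0.01,9.92
Ano,Myristoleic acid,C14:1,0.34,0.03,9.92
Ano,Palmitoleic acid,C16:1,34.61,0.01,9.92
Ano,Ginkgolic acid,C17:1,0.80,0.00,9.92
Ano,Elaidic acid,C18:1n9t,2.26,0.03,9.92
Ano,Oleic acid,C18:1n9c,4.30,0.01,9.92
Ano,Erucic acid,C22:1n9,0.23,0.02,9.92
Ano,Nervonic acid,C24:1n9,0.17,0.02,9.92
Ano,gamma-Linolenic acid,C18:3n6,0.44,0.03,9.92
Ano,Linoleic acid,C18:2n6c,0.49,0.01,9.92
Ano,Arachidonic acid,C20:4n6,10.27,0.02,9.92
Ano,Eicosapentaenoic acid,C20:5n3,1.33,0.02,9.92
Ano,Dihomo-gamma-linolenic acid,C20:3n6,1.45,0.04,9.92
Ano,Eicosadienoic acid,C20:2n6,0.61,0.01,9.92
Ano,Docosahexaenoic acid,C22:6n3,0.95,0.04,9.92
Rho,Caproic acid,C6:0,0.07,0.02,12.72
Rho,Capric acid,C10:0,0.07,0.02,12.72
Rho,Lauric acid,C12:0,0.12,0.01,12.72
Rho,Myristic acid,C14:0,5.95,0.04,12.72
Rho,Pentadecanoic acid,C15:0,0.43,0.02,12.72
Rho,Palmitic acid,C16:0,31.22,0.01,12.72
Rho,Margaric acid,C17:0,0.25,0.04,12.72
Rho,Stearic acid,C18:0,3.30,0.00,12.72
Rho,Behenic acid,C22:0,N.D.,,12.72
Rho,Lignoceric acid,C24:0,N.D.,,12.72
Rho,Myristoleic acid,C14:1,0.12,0.01,12.72
Rho,Palmitoleic acid,C16:1,24.67,0.02,12.72
Rho,Ginkgolic acid,C17:1,0.20,0.00,12.72
Rho,Elaidic acid,C18:1n9t,3.14,0.03,12.72
Rho,Oleic acid,C18:1n9c,7.40,0.00,12.72
Rho,Erucic acid,C22:1n9,N.D.,,12.72
Rho,Nervonic acid,C24:1n9,N.D.,,12.72
Rho,gamma-Linolenic acid,C18:3n6,1.41,0.01,12.72
Rho,Linoleic acid,C18:2n6c,12.58,0.01,12.72
Rho,Arachidonic acid,C20:4n6,5.26,0.03,12.72
Rho,Eicosapentaenoic acid,C20:5n3,2.61,0.01,12.72
Rho,Dihomo-gamma-linolenic acid,C20:3n6,0.51,0.01,12.72
Rho,Eicosadienoic acid,C20:2n6,0.49,0.01,12.72
Rho,Docosahexaenoic acid,C22:6n3,0.20,0.00,12.72
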
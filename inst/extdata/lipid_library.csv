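"name","class","carbons","double_bonds","ether","formula","neutral_mass","mz_MH"
"SM 34:1","SM",34,1,FALSE,"C39H79N2O6P",702.56757489073,701.560298438569
"PE 34:1","PE",34,1,FALSE,"C39H76NO8P",717.53085502892,716.523578576759
"PC 32:0e","PC-E",32,0,TRUE,"C40H82NO7P",719.58289060174,718.575614149579
"PE 36:5e","PE-E",36,5,TRUE,"C41H74NO7P",723.52029034518,722.513013893019
"PE 36:2e","PE-E",36,2,TRUE,"C41H80NO7P",729.5672405376,728.559964085439
"SM 36:1","SM",36,1,FALSE,"C41H83N2O6P",730.59887501901,729.591598566849
"PC 32:0","PC",32,0,FALSE,"C40H80NO8P",733.5621551572,732.554878705039
"PE 36:2","PE",36,2,FALSE,"C41H78NO8P",743.54650509306,742.539228640899
"PE 36:1","PE",36,1,FALSE,"C41H80NO8P",745.5621551572,744.554878705039
"PC 34:1e","PC-E",34,1,TRUE,"C42H84NO7P",745.59854066588,744.591264213719
"PE 38:7e","PE-E",38,7,TRUE,"C43H74NO7P",747.52029034518,746.513013893019
"PG 34:1","PG",34,1,FALSE,"C40H77O10P",748.52543529539,747.518158843229
"PE 38:6e","PE-E",38,6,TRUE,"C43H76NO7P",749.53594040932,748.528663957159
"SM 38:1","SM",38,1,FALSE,"C43H87N2O6P",758.63017514729,757.622898695129
"PC 34:1","PC",34,1,FALSE,"C42H82NO8P",759.57780522134,758.570528769179
"PE 38:4","PE",38,4,FALSE,"C43H78NO8P",767.54650509306,766.539228640899
"PC 36:4e","PC-E",36,4,TRUE,"C44H82NO7P",767.58289060174,766.575614149579
"PG 36:2","PG",36,2,FALSE,"C42H79O10P",774.54108535953,773.533808907369
"PE 40:7e","PE-E",40,7,TRUE,"C45H78NO7P",775.55159047346,774.544314021299
"PE 40:6e","PE-E",40,6,TRUE,"C45H80NO7P",777.5672405376,776.559964085439
"PC 36:4","PC",36,4,FALSE,"C44H80NO8P",781.5621551572,780.554878705039
"PS 36:2","PS",36,2,FALSE,"C42H78NO10P",787.53633433226,786.529057880099
"PC 36:1","PC",36,1,FALSE,"C44H86NO8P",787.60910534962,786.601828897459
"PS 36:1","PS",36,1,FALSE,"C42H80NO10P",789.5519843964,788.544707944239
"PE 40:6","PE",40,6,FALSE,"C45H78NO8P",791.54650509306,790.539228640899
"PC 38:5e","PC-E",38,5,TRUE,"C46H84NO7P",793.59854066588,792.591264213719
"PG 38:4","PG",38,4,FALSE,"C44H79O10P",798.54108535953,797.533808907369
"PC 38:4","PC",38,4,FALSE,"C46H84NO8P",809.59345528548,808.586178833319
"PS 38:4","PS",38,4,FALSE,"C44H78NO10P",811.53633433226,810.529057880099
"SM 42:2","SM",42,2,FALSE,"C47H93N2O6P",812.67712533971,811.669848887549
"PG 40:6","PG",40,6,FALSE,"C46H79O10P",822.54108535953,821.533808907369
"PC 40:6","PC",40,6,FALSE,"C48H84NO8P",833.59345528548,832.586178833319
"PS 40:6","PS",40,6,FALSE,"C46H78NO10P",835.53633433226,834.529057880099
"PI 34:1","PI",34,1,FALSE,"C43H81O13P",836.54147928247,835.534202830309
"PI 36:4","PI",36,4,FALSE,"C45H79O13P",858.52582921833,857.518552766169
"ST 40:1","ST",40,1,FALSE,"C46H89NO11S",863.61563367463,862.608357222469
"PI 36:1","PI",36,1,FALSE,"C45H85O13P",864.57277941075,863.565502958589
"PI 37:4","PI",37,4,FALSE,"C46H81O13P",872.54147928247,871.534202830309
"PI 38:6","PI",38,6,FALSE,"C47H79O13P",882.52582921833,881.518552766169
"PI 38:5","PI",38,5,FALSE,"C47H81O13P",884.54147928247,883.534202830309
"PI 38:4","PI",38,4,FALSE,"C47H83O13P",886.55712934661,885.549852894449
"ST 42:2","ST",42,2,FALSE,"C48H91NO11S",889.63128373877,888.624007286609
"ST 42:1","ST",42,1,FALSE,"C48H93NO11S",891.64693380291,890.639657350749
"PI 40:6","PI",40,6,FALSE,"C49H83O13P",910.55712934661,909.549852894449
"ST 44:2","ST",44,2,FALSE,"C50H95NO11S",917.66258386705,916.655307414889
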
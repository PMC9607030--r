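service,factor,level,healthy,unhealthy
Uber Eats,NZDep,T1,543,1965
Uber Eats,NZDep,T2,607,1905
Uber Eats,NZDep,T3,556,1882
Menulog,NZDep,T1,545,2150
Menulog,NZDep,T2,542,2143
Menulog,NZDep,T3,431,2265
delivereasy,NZDep,T1,501,1362
delivereasy,NZDep,T2,468,1170
delivereasy,NZDep,T3,481,1355
Uber Eats,physical density,T1,623,1928
Uber Eats,physical density,T2,539,1875
Uber Eats,physical density,T3,544,1949
Menulog,physical density,T1,490,2198
Menulog,physical density,T2,462,2231
Menulog,physical density,T3,566,2129
delivereasy,physical density,T1,405,1088
delivereasy,physical density,T2,473,1283
delivereasy,physical density,T3,572,1516
Uber Eats,Maori population,higher_maori,566,1888
Uber Eats,Maori population,other,1140,3864
Menulog,Maori population,higher_maori,448,2250
Menulog,Maori population,other,1070,4308
delivereasy,Maori population,higher_maori,459,1227
delivereasy,Maori population,other,991,2660
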
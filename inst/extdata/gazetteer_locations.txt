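# Location gazetteer: countries, US states, major cities. One entry per line.
United States
United Kingdom
Canada
Australia
Germany
France
Italy
Spain
Netherlands
Belgium
Switzerland
Austria
Sweden
Norway
Denmark
Finland
Ireland
Portugal
Greece
Poland
Czech Republic
Hungary
Russia
China
Japan
South Korea
India
Brazil
Argentina
Mexico
Chile
South Africa
Egypt
Israel
Turkey
Saudi Arabia
New Zealand
Singapore
Thailand
Malaysia
Indonesia
Philippines
Vietnam
Alabama
Alaska
Arizona
Arkansas
California
Colorado
Connecticut
Delaware
Florida
Georgia
Hawaii
Idaho
Illinois
Indiana
Iowa
Kansas
Kentucky
Louisiana
Maine
Maryland
Massachusetts
Michigan
Minnesota
Mississippi
Missouri
Montana
Nebraska
Nevada
New Hampshire
New Jersey
New Mexico
New York
North Carolina
North Dakota
Ohio
Oklahoma
Oregon
Pennsylvania
Rhode Island
South Carolina
South Dakota
Tennessee
Texas
Utah
Vermont
Virginia
Washington
West Virginia
Wisconsin
Wyoming
London
Paris
Berlin
Madrid
Rome
Amsterdam
Stockholm
Copenhagen
Oslo
Helsinki
Dublin
Vienna
Zurich
Geneva
Boston
Chicago
Houston
Philadelphia
Baltimore
Atlanta
Seattle
Toronto
Montreal
Vancouver
Sydney
Melbourne
Tokyo
Beijing
Shanghai
Hong Kong
Seoul
Mumbai
Rotterdam
Leiden
Leeds
Manchester
Edinburgh
Glasgow
Durham
Rochester
Cleveland
Nashville
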